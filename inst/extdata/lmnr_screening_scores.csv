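target_class,combination,sd_sum
pine_oak_mixed,RE4@FEB & SWIR1@FEB,391.40
pine_oak_mixed,RE4@DEC & SWIR1@DEC,456.15
quercus_wutaishanica,NIR@JUN & NIR@OCT,720.60
quercus_wutaishanica,RE4@JUN & RE4@OCT,719.15
scrub_grass,RE2@JUN & RE2@AUG,724.87
scrub_grass,RE3@JUN & RE3@AUG,897.84
scrub_grass,NIR@JUN & NIR@AUG,976.94
scrub_grass,RE4@JUN & RE4@AUG,877.05
shaw,RE2@JUN & RE2@OCT,545.04
shaw,RE3@JUN & RE3@OCT,683.33
shaw,NIR@JUN & NIR@OCT,785.02
shaw,RE4@JUN & RE4@OCT,743.65
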