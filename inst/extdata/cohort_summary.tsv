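quantity	value
n_subjects	50
n_fog_subjects	13
video_minutes_turning	12.88
video_minutes_walking	37.9
video_count	89
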