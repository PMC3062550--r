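# Example pipeline configuration (key = value, '#' comments).
# Defaults shown; any subset may be overridden.
seed = 1
min_58s_identity = 0.6
min_type_identity = 99.5
min_members = 2
bootstrap = 1000
model = jc
min_read_identity = 90
min_read_len = 50
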