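config_hash: 26ddff8b
seed: 1
frackill: 0.1.0
deSolve: 1.40
R: R version 4.3.3 (2024-02-29)
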