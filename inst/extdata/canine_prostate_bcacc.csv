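cls,bcacc
cancer,0.88
lymphocyte,0.95
stromal,0.87
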