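>vtp_synth_1 synthetic vesicular transport-like example
MKAVLDERTGHILKMFPSTW
>nonvtp_synth_2 synthetic negative example
ACDEFGHIKLMNPQRSTVWY
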