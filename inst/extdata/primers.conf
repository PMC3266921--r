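# Universal bacterial 16S rRNA gene primer pair; the forward primer carries
# the fluorescent label, so the forward end defines the detected fragment.
forward = AGAGTTTGATCMTGGCTCAG
reverse = GGTTACCTTGTTACGACTT
max_mismatch = 0
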