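# Five-point example instance; its two homometric solutions are
# {0, 2, 7, 8, 10} and {0, 2, 3, 8, 10}.
1 2 2 3 5 6 7 8 8 10
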