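4ae1c4f26f10a8966b26a1a43971e5fa
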