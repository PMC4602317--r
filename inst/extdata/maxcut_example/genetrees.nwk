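((a1,d1),c1);
((d1,b1),e1);
((c1,e1),f1);
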