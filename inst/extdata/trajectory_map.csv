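initial_prefix,final_prefix,category
S41,S42,other
S42,S41,other
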