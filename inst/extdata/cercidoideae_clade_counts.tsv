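type	total	duplication_mrca
c>=2,b>=2	249	212
c>=2,b=1	425	183
c=1,b>=2	3205	2036
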