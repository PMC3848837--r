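90-102
126-131
224-233
292-297
313-328
381-388
681-686
745-767
784-794
891-918
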