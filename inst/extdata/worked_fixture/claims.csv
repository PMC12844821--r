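product_id,claim_text
WF014,family pack
WF025,locally produced
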