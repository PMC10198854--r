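TLS13	13-chemokine TLS signature	CCL2	CCL3	CCL4	CCL5	CCL18	CCL19	CCL21	CXCL9	CXCL10	CXCL11	CXCL13	CXCR4	LAMP3
synthetic_exhausted_T	synthetic stand-in marker set (not a published signature)	MODN01	MODN02	MODN03	MODN04	MODN05
synthetic_stromal	synthetic stand-in marker set (not a published signature)	MODP01	MODP02	MODP03	MODP04	MODP05	MODP06
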