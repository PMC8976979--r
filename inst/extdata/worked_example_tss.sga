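chrW	TSS	926	+	1	synthP01
chrW	TSS	1253	-	1	synthP02
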