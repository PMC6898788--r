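MHC_II	MHC class II HLA genes	HLA-DMA	HLA-DMB	HLA-DOA	HLA-DOB	HLA-DPA1	HLA-DPB1	HLA-DQA1	HLA-DQA2	HLA-DQB1	HLA-DQB2	HLA-DRA	HLA-DRB1	HLA-DRB5
MHC_I	MHC class I HLA and antigen-loading genes	HLA-A	HLA-B	HLA-C	HLA-E	HLA-F	TAP1	TAP2	B2M
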