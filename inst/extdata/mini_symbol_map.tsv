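symbol	entrez_id
CD19	930
MS4A1	931
CD22	933
CD79A	974
CD3D	915
CD3E	916
CD4	920
CD8A	925
CD14	929
CSF1R	1436
FCN1	2322
GFAP	2670
SLC1A3	2596
RBFOX3	4744
SNAP25	4747
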