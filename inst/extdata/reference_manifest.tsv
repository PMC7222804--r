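accession	species	group	length_bp
NC_001328.1	Caenorhabditis elegans	invertebrate	13794
NC_024511.2	Drosophila melanogaster	invertebrate	19524
NC_026914.1	Daphnia magna	invertebrate	14948
NC_001804.1	Latimeria chalumnae	vertebrate	16407
NC_002333.2	Danio rerio	vertebrate	16596
NC_005797.1	Ambystoma mexicanum	vertebrate	16369
NC_040970.1	Gallus gallus	vertebrate	16785
NC_005089.1	Mus musculus	vertebrate	16299
NC_002008.4	Canis lupus familiaris	vertebrate	16727
NC_008143.1	Crocodylus porosus	vertebrate	16916
KM679417.1	Pan troglodytes ellioti	vertebrate	16559
NC_012920.1	Homo sapiens	vertebrate	16569
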