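file	md5
anthocyanin_registry.tsv	9b8cf3371c1e35e1f286f7531746277b
dpph_activities.tsv	29a4d7d72815d41772d31084d67daac0
bde_table.tsv	800531c7f0ac4d52a122333bbbd5b047
mopac_example_synthetic.out	c17d74deb51e1997b12f04add3675953
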