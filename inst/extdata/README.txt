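callitrichid_tree_approx.nwk
    25-species composite callitrichid phylogeny used as a topology fixture.
    The clade structure follows the published composite phylogeny of the
    study system; branch lengths are APPROXIMATE plausible divergence times
    in millions of years. Only topology-dependent analyses (parsimony
    ancestral-state reconstruction) should be asserted against this file.
callitrichid_locomotion.csv
    Locomotor category (VCL = vertical clinging and leaping, HL =
    horizontal leaping) for each of the 25 species, from the published
    species table.
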