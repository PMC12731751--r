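name,formula,monoisotopic_mass
D-tryptophan,C11H12N2O2,204.089878
hypoxanthine,C5H4N4O,136.038511
bilirubin,C33H36N4O6,584.263484
phosphoric acid,H3PO4,97.976898
phthalic acid,C8H6O4,166.026609
carbamic acid,CH3NO2,61.016378
2-methylglutaric acid,C6H10O4,146.057909
tetrahydroisoquinoline,C9H11N,133.089149
debrisoquine,C10H13N3,175.110947
4-nitrobenzoic acid,C7H5NO4,167.021858
sulfadimethoxine,C12H14N4O4S,310.073609
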