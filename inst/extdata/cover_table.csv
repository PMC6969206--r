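species,lineage,site,cover,sd,category,western_fraction
Perna perna,west,P1,0.14,0.27,edge,1
Perna perna,west,P2,0.12,0.22,edge,1
Perna perna,west,P3,57.49,12.41,centre,1
Perna perna,west,P4,59.46,13.98,centre,1
Perna perna,both,P5,66.2,26.61,edge,0.5
Perna perna,both,P6,52.1,25.7,edge,0.3
Perna perna,east,P7,71.65,20.91,centre,0
Perna perna,east,P8,73.53,26.88,centre,0
Mytilus galloprovincialis,mytilus,M1,38.19,14.67,centre,
Mytilus galloprovincialis,mytilus,M2,40.22,17.76,centre,
Mytilus galloprovincialis,mytilus,M3,0.32,0.41,edge,
Mytilus galloprovincialis,mytilus,M4,0.15,0.29,edge,
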