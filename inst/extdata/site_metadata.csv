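species,lineage,site_name,code,lat,lon,n,category
Perna perna,west,Kleinmond,P1,-34.33,19.01,47,edge
Perna perna,west,Gansbaai,P2,-34.60,19.34,47,edge
Perna perna,west,Mossel Bay,P3,-34.19,22.11,47,centre
Perna perna,west,Brenton-on-Sea,P4,-34.07,23.02,45,centre
Perna perna,both,Kidd's Beach,P5,-33.15,27.70,46,edge
Perna perna,both,Haga Haga,P6,-32.76,28.25,41,edge
Perna perna,east,Umzumbe,P7,-30.61,30.55,48,centre
Perna perna,east,Nonoti,P8,-29.67,30.66,47,centre
Perna perna,east,Cape St Lucia,P9,-28.51,32.41,47,centre
Mytilus galloprovincialis,mytilus,Mossel Bay,M1,-34.19,22.11,48,centre
Mytilus galloprovincialis,mytilus,Brenton-on-Sea,M2,-34.07,23.02,48,centre
Mytilus galloprovincialis,mytilus,Port Alfred,M3,-33.60,26.89,48,edge
Mytilus galloprovincialis,mytilus,Kidd's Beach,M4,-33.15,27.70,48,edge
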