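"month","region","hours_per_km2"
"2021-06","West",1197.6
"2021-07","West",1716.4
"2021-08","West",683.9
"2021-09","West",825.4
"2021-10","West",1328.8
"2021-11","West",928.1
"2021-12","West",598.7
"2022-01","West",1303.8
"2022-02","West",2445.8
"2022-03","West",1523.4
"2022-04","West",1668.5
"2022-05","West",1119.7
"2022-06","West",1553.2
"2022-07","West",1651.1
"2022-08","West",2351.3
"2022-09","West",2704.5
"2022-10","West",1579.2
"2022-11","West",910.6
"2022-12","West",2347.8
"2023-01","West",1767.8
"2023-02","West",686.6
"2023-03","West",1025.5
"2023-04","West",2272.8
"2023-05","West",1020.1
"2023-06","West",1706.6
"2023-07","West",2309.5
"2023-08","West",1547.9
"2023-09","West",1412.2
"2023-10","West",970.4
"2023-11","West",1789
"2023-12","West",930.4
"2024-01","West",1765.9
"2024-02","West",1254
"2024-03","West",1507.9
"2024-04","West",1201.1
"2024-05","West",1578.8
"2024-06","West",1163
"2024-07","West",723
"2024-08","West",1765.6
"2024-09","West",799.7
"2021-06","East",137.5
"2021-07","East",185.3
"2021-08","East",180.7
"2021-09","East",13.3
"2021-10","East",212.9
"2021-11","East",202.1
"2021-12","East",213.3
"2022-01","East",192.3
"2022-02","East",326.4
"2022-03","East",128.5
"2022-04","East",197
"2022-05","East",228.4
"2022-06","East",165.2
"2022-07","East",138.2
"2022-08","East",207.2
"2022-09","East",163.8
"2022-10","East",247.7
"2022-11","East",224.4
"2022-12","East",245.4
"2023-01","East",151.9
"2023-02","East",138.5
"2023-03","East",169.1
"2023-04","East",95.7
"2023-05","East",246.6
"2023-06","East",5
"2023-07","East",24.6
"2023-08","East",83.8
"2023-09","East",55.1
"2023-10","East",475.3
"2023-11","East",367.4
"2023-12","East",293.6
"2024-01","East",121.8
"2024-02","East",288.2
"2024-03","East",79.8
"2024-04","East",5
"2024-05","East",188.9
"2024-06","East",228
"2024-07","East",372.2
"2024-08","East",204.4
"2024-09","East",197.6
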