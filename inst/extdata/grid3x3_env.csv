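"edge_id","sidewalk_width","on_street_parking","sidewalk_walkability","traffic_signals","driveway_width","dh_ratio","green_spaces","street_walls","garbage_bins","streetlights","benches","shops","life_facilities","bus_stops","leisure_facilities"
"s01",1.92,2,3,0,9.52,0.9,1,2,3,4,1,0.138,0.205,0.033,0.005
"s02",1.98,1,1,1,10.62,1.12,3,2,5,1,4,0.061,0.029,0.02,0.192
"s03",2.71,3,1,1,9.85,0.85,1,1,3,1,1,0.04,0.104,0.016,0.008
"s04",1.91,3,2,2,6.72,0.46,3,1,2,9,0,0.218,0.325,0.039,0.099
"s05",1.05,1,3,0,6.14,0.72,3,2,2,4,1,0.268,0.067,0.051,0.12
"s06",2.32,2,3,0,6.98,0.54,1,2,1,4,1,0.259,0.203,0.028,0.055
"s07",1.59,1,3,0,9.91,0.69,2,2,4,2,0,0.239,0.162,0.072,0.059
"s08",2.53,1,2,0,4.82,0.76,3,2,4,1,2,0.203,0.118,0.052,0.113
"s09",2.51,3,3,0,6.02,1.01,2,2,1,6,0,0.274,0.024,0.036,0
"s10",1.44,2,1,2,8.31,0.72,2,0,5,5,0,0.525,0.105,0.109,0.119
"s11",2.1,3,3,1,6.68,1.68,2,2,0,2,2,0.133,0.043,0.009,0.002
"s12",1.98,2,2,0,4.84,1.52,3,1,4,2,2,0.1,0.138,0.008,0.018
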