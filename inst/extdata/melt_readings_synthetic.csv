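temperature_C,i_vv,i_vh,i_hv,i_hh,replicate
20,1003.5145448,398.3130792,1107.396220,992.5957064,1
23,1002.9945174,393.7635792,1093.784661,998.7291312,1
26,994.4623597,396.4455139,1099.674119,1000.8809420,1
29,998.1629093,397.7559647,1096.053263,999.4557645,1
31,991.3495697,396.8299792,1093.417473,1002.8921806,1
33,996.4753709,395.3845302,1111.300818,995.7886425,1
35,1005.4979475,405.4654429,1095.188995,999.6615903,1
37,1009.5934430,432.5846066,1099.742165,1002.9709985,1
39,1002.7156061,520.5507855,1098.384883,994.9320657,1
41,1001.0172752,658.8323842,1092.803580,991.3072094,1
43,995.6400576,718.6500456,1099.789212,1000.2594577,1
45,993.0938908,737.2867091,1105.955949,996.7090529,1
47,1007.7848990,738.4872817,1104.890530,1000.8340884,1
49,996.2679100,740.2790584,1086.825371,996.5473460,1
51,996.8746644,740.5013975,1115.521497,1002.3146483,1
20,1003.7348883,397.4820148,1113.001485,996.1379211,2
23,1006.6617125,398.6660858,1098.357879,1001.5838606,2
26,1006.6105926,398.1965600,1093.471504,1005.3268476,2
29,998.7302098,399.7311616,1086.753684,1003.2038129,2
31,999.6027999,401.4066294,1096.857263,994.2562125,2
33,998.7901633,397.6972433,1090.447679,1004.5988940,2
35,1001.9701945,406.8448247,1105.648629,1007.7459143,2
37,995.2761423,428.5419157,1104.109011,1008.9511131,2
39,997.9325885,523.1554402,1099.533381,995.1322787,2
41,998.7127922,649.6327731,1101.294958,1011.3945406,2
43,996.9129607,714.9080145,1102.788462,999.0675200,2
45,1010.3525330,735.1905188,1101.174911,997.2906271,2
47,1008.3328646,741.6903054,1104.290789,998.9635444,2
49,1000.0922882,741.1306240,1105.043350,1000.1052191,2
51,1003.0284677,742.8020608,1095.268815,1001.2432015,2
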