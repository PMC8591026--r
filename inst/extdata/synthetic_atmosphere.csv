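"year","co2_ppm","d13c_atm_permil"
1850,285,-6.4
1851,285.097,-6.4017
1852,285.196,-6.4034
1853,285.297,-6.4052
1854,285.4,-6.407
1855,285.505,-6.4088
1856,285.613,-6.4107
1857,285.722,-6.4126
1858,285.833,-6.4145
1859,285.946,-6.4165
1860,286.062,-6.4185
1861,286.18,-6.4205
1862,286.3,-6.4226
1863,286.423,-6.4247
1864,286.548,-6.4269
1865,286.675,-6.4291
1866,286.805,-6.4314
1867,286.937,-6.4337
1868,287.072,-6.436
1869,287.209,-6.4384
1870,287.35,-6.4409
1871,287.493,-6.4433
1872,287.638,-6.4459
1873,287.787,-6.4485
1874,287.938,-6.4511
1875,288.093,-6.4538
1876,288.25,-6.4565
1877,288.411,-6.4593
1878,288.574,-6.4622
1879,288.741,-6.4651
1880,288.911,-6.468
1881,289.084,-6.471
1882,289.261,-6.4741
1883,289.441,-6.4772
1884,289.624,-6.4804
1885,289.812,-6.4837
1886,290.002,-6.487
1887,290.197,-6.4904
1888,290.395,-6.4938
1889,290.597,-6.4973
1890,290.804,-6.5009
1891,291.014,-6.5046
1892,291.228,-6.5083
1893,291.446,-6.5121
1894,291.669,-6.516
1895,291.896,-6.5199
1896,292.127,-6.5239
1897,292.363,-6.5281
1898,292.603,-6.5322
1899,292.848,-6.5365
1900,293.098,-6.5408
1901,293.353,-6.5453
1902,293.613,-6.5498
1903,293.877,-6.5544
1904,294.147,-6.5591
1905,294.422,-6.5639
1906,294.703,-6.5687
1907,294.989,-6.5737
1908,295.28,-6.5788
1909,295.578,-6.584
1910,295.881,-6.5892
1911,296.189,-6.5946
1912,296.504,-6.6001
1913,296.825,-6.6057
1914,297.152,-6.6113
1915,297.486,-6.6171
1916,297.826,-6.6231
1917,298.173,-6.6291
1918,298.526,-6.6352
1919,298.886,-6.6415
1920,299.254,-6.6479
1921,299.628,-6.6544
1922,300.01,-6.661
1923,300.399,-6.6678
1924,300.796,-6.6747
1925,301.2,-6.6817
1926,301.612,-6.6889
1927,302.033,-6.6962
1928,302.461,-6.7037
1929,302.898,-6.7113
1930,303.343,-6.719
1931,303.797,-6.7269
1932,304.26,-6.735
1933,304.732,-6.7432
1934,305.213,-6.7515
1935,305.703,-6.7601
1936,306.203,-6.7687
1937,306.713,-6.7776
1938,307.232,-6.7866
1939,307.762,-6.7959
1940,308.302,-6.8052
1941,308.852,-6.8148
1942,309.413,-6.8246
1943,309.985,-6.8345
1944,310.568,-6.8447
1945,311.163,-6.855
1946,311.769,-6.8655
1947,312.387,-6.8763
1948,313.017,-6.8872
1949,313.659,-6.8984
1950,314.313,-6.9098
1951,314.981,-6.9214
1952,315.661,-6.9332
1953,316.354,-6.9453
1954,317.061,-6.9576
1955,317.782,-6.9701
1956,318.517,-6.9829
1957,319.266,-6.9959
1958,320.03,-7.0092
1959,320.808,-7.0227
1960,321.602,-7.0366
1961,322.411,-7.0506
1962,323.236,-7.065
1963,324.076,-7.0796
1964,324.934,-7.0945
1965,325.807,-7.1097
1966,326.698,-7.1252
1967,327.606,-7.141
1968,328.532,-7.1571
1969,329.476,-7.1735
1970,330.438,-7.1902
1971,331.419,-7.2073
1972,332.419,-7.2247
1973,333.439,-7.2424
1974,334.478,-7.2605
1975,335.537,-7.2789
1976,336.617,-7.2977
1977,337.718,-7.3168
1978,338.841,-7.3364
1979,339.985,-7.3563
1980,341.152,-7.3766
1981,342.341,-7.3972
1982,343.553,-7.4183
1983,344.789,-7.4398
1984,346.049,-7.4617
1985,347.334,-7.4841
1986,348.643,-7.5068
1987,349.978,-7.5301
1988,351.339,-7.5537
1989,352.727,-7.5779
1990,354.141,-7.6025
1991,355.583,-7.6275
1992,357.053,-7.6531
1993,358.551,-7.6792
1994,360.079,-7.7057
1995,361.636,-7.7328
1996,363.224,-7.7604
1997,364.842,-7.7886
1998,366.492,-7.8173
1999,368.174,-7.8465
2000,369.889,-7.8763
2001,371.637,-7.9067
2002,373.419,-7.9377
2003,375.236,-7.9693
2004,377.088,-8.0015
2005,378.976,-8.0344
2006,380.901,-8.0678
2007,382.864,-8.102
2008,384.864,-8.1368
2009,386.903,-8.1722
2010,388.982,-8.2084
2011,391.102,-8.2453
2012,393.263,-8.2828
2013,395.465,-8.3211
2014,397.711,-8.3602
2015,400,-8.4
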