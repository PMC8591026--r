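t001    1864    84   130   117   150   202   178
t001    1870   180   111   226    94   135    98    78    81    58    37
t001    1880    38    59    52    45    68    45    68    67   107   108
t001    1890   153   155   203    68   141   106   126   148    95   152
t001    1900   152   167    86    83    59    73   101    76    75    54
t001    1910    41    51    75    42    74    48    65    92   137    91
t001    1920    92    64    70   111   123   110    86    92    78    80
t001    1930   126   171   187   137    93    75    83    51    65   101
t001    1940   165   157   149   128    63   102    81   159   177   310
t001    1950   302   213   195   144   126    89    85   123   130    90
t001    1960    87    65   169   200   186   169   189    79    77   125
t001    1970    86    97   104   178   173   116   120    82   103   159
t001    1980   105   113    66    65    82    81    77    73   145    82
t001    1990    80    94    94    50    99    52    92   172   206   151
t001    2000   118   102    89   115   138   106   122   106   119   112
t001    2010   100    98    83   108    87    47   999
t002    1898   189   204
t002    1900   187   197   116    83    71    97    72    60    67    40
t002    1910    64    63    85    95   106   170   134   147   210   115
t002    1920   187   114   146   130   177   101   119   103   100   170
t002    1930   145   172   225   190   150   159   116   214   133   133
t002    1940   169   100   142    97   142   172   135   167   160   148
t002    1950   223    83   155   120   160   159   174   155   182   241
t002    1960   235   207   215   263   181   181   251   196   251   182
t002    1970   238   291   207   321   303   231   274   186   281   206
t002    1980   265   188   126   176   176   140   101   130   148   109
t002    1990   118   108   151   111    91    77    67   100    80    91
t002    2000    96    69   141    91   247   190   208   193   211   145
t002    2010   216   158   136   157   100   134   999
t003    1879    57
t003    1880    30    32    20    39    53    80    50    60   105    61
t003    1890    76    75   129    77   108   135   155   120   181   168
t003    1900   148    94   114   140   125   110    95   117    71   122
t003    1910    80   104    95    51    81   115    50    64   139    87
t003    1920   130   133   120   125   131    77    72    75    68    45
t003    1930    64    58    53    80    77    55    99    91   122   185
t003    1940   112   101    83    74    80   120    87   148   113   126
t003    1950   189   122   153    98   120   107    58    98   128   136
t003    1960    66    63    72   128    69    83   123   184   223   115
t003    1970    47    49    65    68    79   105   140   129   101   104
t003    1980   114   145   116   108   127   316   272   304   210   253
t003    1990   168   187   252   153   190   236   110   122    63    64
t003    2000    65    60    47    38    59    58    48    41    61   114
t003    2010    84    69    76    63   100   179   999
t004    1900   110    77    81    73    61    93   150    99   108   108
t004    1910   171   127    87    75   109   112   121   155    97   188
t004    1920   125   136   139   160   159   132   140   131   153   212
t004    1930   158   118   147   101   129    71    88    56    66    81
t004    1940    53    63    65    47    57    74    97    66    58    56
t004    1950    44    35    58    75    45    66   125   115   106   159
t004    1960   116   105    97   127   182   284   253   201   248   143
t004    1970   153   105   195   164   148    99   101    80    56    60
t004    1980    49    73    48    43    48    53    49    66    85    86
t004    1990    81    88    82   130   112   125   134   111   160   106
t004    2000   106   102   112    97   116   123   227   305   247   341
t004    2010   352   579   245   269   211   291   999
t005    1877    98   130   149
t005    1880    84    95   121    78   122    98   163   287   251   123
t005    1890   193   154    97   118   129   152   145   127   206    85
t005    1900   143   120    70   109   156   178   208   139   106    88
t005    1910   147   244   127   234   184   126   132   120   122   163
t005    1920   116   123    94    72   113   116   117    93    84   106
t005    1930   118    95   122   129    90   111    72    92    62    94
t005    1940   196   236   132    78    97    99    97    57    87    99
t005    1950   111   196   170   141   114    59    55   136    86    95
t005    1960   136   103   120   110   210   134   113   110    96    79
t005    1970    71    63   105   126   143    85   140   158    72    77
t005    1980    72   108   103   133    88    97   107   107   161    76
t005    1990    87    79    66    63    41    83   107    47    86    64
t005    2000    94   124   107   162   132   178   283   227   192   254
t005    2010   298   250   214   103   271   247   999
t006    1901    87   102   103   115   142   102   135   129   146
t006    1910   134   152    82   122   146   129   137   154   114   101
t006    1920    80    75    90    98   151   128   136   128    92   107
t006    1930   125   202   273   162   234   144   200   202   205   144
t006    1940   179   160   183   129   156   143   102   112    96   116
t006    1950    97   105    77    39    51    71    70    62    81   173
t006    1960    85   217   102   111   109   166   105   128   146   140
t006    1970   155   121   122   103    93    81   109   173   120   105
t006    1980    71   135   114   101    81    66   113    91   153   137
t006    1990   164   127   168    97    71   104   118    89    76    67
t006    2000    69   125   161   119   121   163    73    72    59   145
t006    2010    83   129   122    86    71    67   999
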