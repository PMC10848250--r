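api,corina_r3m,disperses,experimental_amorphous_density,predicted_amorphous_density,crystallographic_density,ccdc_refcode
propranolol,0.342,0,NA,1.08,1.164,IMITON
cimetidine,0.403,0,NA,1.20,1.312,CIMETD
melatonin,0.407,0,NA,1.16,1.276,MELATN01
terfenadine,0.561,0,NA,1.04,1.13,EWEMIF
cloperastine,0.562,0,NA,1.11,NA,NA
nifedipine,0.568,0,1.20,1.23,1.382,BICCIZ03
quinidine,0.593,0,1.17,1.14,1.234,BOMDUC
sulfanilamide,0.595,0,NA,1.44,1.514,SULAMD03
tolbutamide,0.687,1,NA,1.21,1.252,ZZZPUS18
indomethacin,0.737,1,1.31,1.29,1.372,INDMET
ketoconazole,0.814,1,1.27,1.30,1.4,KCONAZ
itraconazole,0.872,1,1.27,1.26,1.36,TEHZIP
chlorpropamide,0.927,1,NA,1.36,1.45,BEDMIG10
felodipine,0.964,1,1.28,1.26,1.451,DONTIJ
bicalutamide,1.001,1,NA,1.43,1.554,JAYCES
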