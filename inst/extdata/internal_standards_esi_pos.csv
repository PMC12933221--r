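identifier,name,mz,rt,rt_unit,polarity,role,ms2_key
benzothiazole_d4,Benzothiazole-d4,124.0807,333.59999999999997,seconds,positive,internal_standard,NA
lidocaine_d10,Lidocaine-d10,245.2433,318.59999999999997,seconds,positive,internal_standard,NA
chloridazon_d5,Chloridazon-d5,227.0743,390,seconds,positive,internal_standard,NA
irbesartan_d4,Irbesartan-d4,433.2648,532.1999999999999,seconds,positive,internal_standard,NA
darunavir_d9,Darunavir-d9,557.299,624.6,seconds,positive,internal_standard,NA
propazine_d6,Propazine-d6,236.1544,660,seconds,positive,internal_standard,NA
azoxystrobin_d4,Azoxystrobin-d4,408.1492,708,seconds,positive,internal_standard,NA
diazinon_d10,Diazinon-d10,315.1711,846,seconds,positive,internal_standard,NA
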