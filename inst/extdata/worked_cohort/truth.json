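{"samples":{"sample_id":["S01","S02","S03","S04","S05","S06","S07","S08","S09","S10","S11","S12"],"phenotype":["infiltrated","infiltrated","infiltrated","infiltrated","excluded","excluded","excluded","desert","desert","desert","desert","desert"],"true_R":[193.13207915828,237.697286480094,167.630546142402,273.130005674953,203.960780543711,246.221445044903,172.626765016321,10,6.40312423743285,3.60555127546399,12.2065556157337,0],"true_theta":[0.370891288812662,0.388318718172466,0.302884868374971,0.414506874584786,1.37340076694502,1.34551954758084,1.39612412778666,0.643501108793284,0.674740942223553,0.588002603547568,0.610725964389209,0]},"genes":{"gene_id":["CYT_01","CYT_02","CYT_03","CYT_04","CYT_05","CYT_06","CYT_07","CYT_08","CYT_09","CYT_10","AP_01","AP_02","AP_03","AP_04","AP_05","AP_06","AP_07","AP_08","TGFB_01","TGFB_02","TGFB_03","TGFB_04","TGFB_05","TGFB_06","TGFB_07","TGFB_08","DES_01","DES_02","DES_03","DES_04","DES_05","DES_06","DES_07","DES_08","ACTB","ACTG1","HSP90AB1","UBC","NOISE_01","NOISE_02","NOISE_03","NOISE_04","NOISE_05","NOISE_06","NOISE_07","NOISE_08","NOISE_09","NOISE_10","NOISE_11","NOISE_12","NOISE_13","NOISE_14","NOISE_15","NOISE_16","NOISE_17","NOISE_18","NOISE_19","NOISE_20","NOISE_21","NOISE_22"],"module":["cytotoxic","cytotoxic","cytotoxic","cytotoxic","cytotoxic","cytotoxic","cytotoxic","cytotoxic","cytotoxic","cytotoxic","antigen_presentation","antigen_presentation","antigen_presentation","antigen_presentation","antigen_presentation","antigen_presentation","antigen_presentation","antigen_presentation","tgfb_stroma","tgfb_stroma","tgfb_stroma","tgfb_stroma","tgfb_stroma","tgfb_stroma","tgfb_stroma","tgfb_stroma","desert_program","desert_program","desert_program","desert_program","desert_program","desert_program","desert_program","desert_program","housekeeping","housekeeping","housekeeping","housekeeping","noise","noise","noise","noise","noise","noise","noise","noise","noise","noise","noise","noise","noise","noise","noise","noise","noise","noise","noise","noise","noise","noise"]}}
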