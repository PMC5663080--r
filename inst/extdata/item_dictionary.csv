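"item","domain","min_code","max_code","special_codes","probs","loadings","noise_sd","fs_dependent","set_adl9","set_iadl_perf7","set_iadl_cap7","set_mood9"
"adl_bed_mobility","adl",0,4,"8","0.760;0.100;0.065;0.045;0.030","0.9;0.1;0.0;0.0;0.1",0.52,TRUE,TRUE,FALSE,FALSE,FALSE
"adl_transfer","adl",0,4,"8","0.760;0.100;0.065;0.045;0.030","0.9;0.1;0.0;0.0;0.1",0.52,TRUE,TRUE,FALSE,FALSE,FALSE
"adl_locomotion","adl",0,4,"8","0.760;0.100;0.065;0.045;0.030","0.9;0.1;0.0;0.0;0.1",0.52,TRUE,TRUE,FALSE,FALSE,FALSE
"adl_dressing","adl",0,4,"8","0.760;0.100;0.065;0.045;0.030","0.9;0.1;0.0;0.0;0.1",0.52,TRUE,TRUE,FALSE,FALSE,FALSE
"adl_eating","adl",0,4,"8","0.840;0.070;0.045;0.027;0.018","0.9;0.1;0.0;0.0;0.1",0.56,TRUE,TRUE,FALSE,FALSE,FALSE
"adl_toilet_use","adl",0,4,"8","0.760;0.100;0.065;0.045;0.030","0.9;0.1;0.0;0.0;0.1",0.52,TRUE,TRUE,FALSE,FALSE,FALSE
"adl_hygiene","adl",0,4,"8","0.760;0.100;0.065;0.045;0.030","0.9;0.1;0.0;0.0;0.1",0.52,TRUE,TRUE,FALSE,FALSE,FALSE
"adl_bathing","adl",0,4,"8","0.55;0.12;0.11;0.12;0.10","0.9;0.1;0.0;0.0;0.1",0.62,TRUE,TRUE,FALSE,FALSE,FALSE
"adl_locomotion_outside","adl",0,4,"8","0.60;0.12;0.10;0.10;0.08","0.9;0.1;0.0;0.0;0.1",0.68,TRUE,TRUE,FALSE,FALSE,FALSE
"iadl_meal_prep_perf","iadl_performance",0,3,"8","0.16;0.18;0.26;0.40","0.62;0.30;0.00;0.00;0.10",0.36,FALSE,FALSE,TRUE,FALSE,FALSE
"iadl_housework_perf","iadl_performance",0,3,"8","0.12;0.16;0.27;0.45","0.62;0.30;0.00;0.00;0.10",0.36,FALSE,FALSE,TRUE,FALSE,FALSE
"iadl_phone_perf","iadl_performance",0,3,"8","0.55;0.20;0.15;0.10","0.62;0.30;0.00;0.00;0.10",0.48,FALSE,FALSE,TRUE,FALSE,FALSE
"iadl_shopping_perf","iadl_performance",0,3,"8","0.12;0.18;0.25;0.45","0.62;0.30;0.00;0.00;0.10",0.65,FALSE,FALSE,TRUE,FALSE,FALSE
"iadl_transport_perf","iadl_performance",0,3,"8","0.16;0.20;0.26;0.38","0.62;0.30;0.00;0.00;0.10",0.65,FALSE,FALSE,TRUE,FALSE,FALSE
"iadl_meds_perf","iadl_performance",0,3,"8","0.45;0.20;0.20;0.15","0.62;0.30;0.00;0.00;0.10",0.75,FALSE,FALSE,TRUE,FALSE,FALSE
"iadl_finances_perf","iadl_performance",0,3,"8","0.35;0.20;0.20;0.25","0.62;0.30;0.00;0.00;0.10",0.75,FALSE,FALSE,TRUE,FALSE,FALSE
"iadl_meal_prep_cap","iadl_capacity",0,2,"","0.22;0.28;0.50","0.62;0.20;0.00;0.00;0.10",0.3,FALSE,FALSE,FALSE,TRUE,FALSE
"iadl_housework_cap","iadl_capacity",0,2,"","0.16;0.26;0.58","0.62;0.20;0.00;0.00;0.10",0.3,FALSE,FALSE,FALSE,TRUE,FALSE
"iadl_phone_cap","iadl_capacity",0,2,"","0.60;0.22;0.18","0.62;0.20;0.00;0.00;0.10",0.42,FALSE,FALSE,FALSE,TRUE,FALSE
"iadl_shopping_cap","iadl_capacity",0,2,"","0.16;0.24;0.60","0.62;0.20;0.00;0.00;0.10",0.55,FALSE,FALSE,FALSE,TRUE,FALSE
"iadl_transport_cap","iadl_capacity",0,2,"","0.22;0.28;0.50","0.62;0.20;0.00;0.00;0.10",0.55,FALSE,FALSE,FALSE,TRUE,FALSE
"iadl_meds_cap","iadl_capacity",0,2,"","0.50;0.28;0.22","0.62;0.20;0.00;0.00;0.10",0.6,FALSE,FALSE,FALSE,TRUE,FALSE
"iadl_finances_cap","iadl_capacity",0,2,"","0.40;0.28;0.32","0.62;0.20;0.00;0.00;0.10",0.6,FALSE,FALSE,FALSE,TRUE,FALSE
"mood_negative_statements","mood",0,3,"","0.84;0.08;0.05;0.03","0.10;0.05;0.70;0.00;0.05",0.78,FALSE,FALSE,FALSE,FALSE,TRUE
"mood_anger","mood",0,3,"","0.88;0.06;0.04;0.02","0.10;0.05;0.70;0.00;0.05",0.78,FALSE,FALSE,FALSE,FALSE,TRUE
"mood_unrealistic_fears","mood",0,3,"","0.90;0.05;0.03;0.02","0.10;0.05;0.70;0.00;0.05",0.78,FALSE,FALSE,FALSE,FALSE,TRUE
"mood_health_complaints","mood",0,3,"","0.74;0.12;0.09;0.05","0.10;0.05;0.70;0.00;0.05",0.78,FALSE,FALSE,FALSE,FALSE,TRUE
"mood_anxious_complaints","mood",0,3,"","0.78;0.10;0.07;0.05","0.10;0.05;0.70;0.00;0.05",0.78,FALSE,FALSE,FALSE,FALSE,TRUE
"mood_sad_expression","mood",0,3,"","0.82;0.09;0.06;0.03","0.10;0.05;0.70;0.00;0.05",0.78,FALSE,FALSE,FALSE,FALSE,TRUE
"mood_crying","mood",0,3,"","0.90;0.05;0.03;0.02","0.10;0.05;0.70;0.00;0.05",0.78,FALSE,FALSE,FALSE,FALSE,TRUE
"mood_withdrawal","mood",0,3,"","0.85;0.08;0.04;0.03","0.10;0.05;0.70;0.00;0.05",0.95,FALSE,FALSE,FALSE,FALSE,TRUE
"mood_reduced_interaction","mood",0,3,"","0.84;0.09;0.04;0.03","0.10;0.05;0.70;0.00;0.05",0.95,FALSE,FALSE,FALSE,FALSE,TRUE
"cog_short_term_memory","cognition",0,1,"","0.72;0.28","0.05;0.85;0.00;0.00;0.00",0.55,FALSE,FALSE,FALSE,FALSE,FALSE
"cog_decision_making","cognition",0,3,"","0.66;0.24;0.07;0.03","0.05;0.90;0.00;0.00;0.00",0.45,FALSE,FALSE,FALSE,FALSE,FALSE
"cog_making_self_understood","cognition",0,3,"","0.79;0.13;0.05;0.03","0.05;0.85;0.00;0.00;0.00",0.6,FALSE,FALSE,FALSE,FALSE,FALSE
"cog_comatose","cognition",0,1,"","0.998;0.002","0.0;0.6;0.0;0.0;0.3",0.8,FALSE,FALSE,FALSE,FALSE,FALSE
"pain_frequency","pain",0,2,"","0.45;0.30;0.25","0.1;0.0;0.0;0.9;0.0",0.45,FALSE,FALSE,FALSE,FALSE,FALSE
"pain_intensity","pain",0,3,"","0.45;0.19;0.25;0.11","0.05;0.00;0.00;0.90;0.00",0.5,FALSE,FALSE,FALSE,FALSE,FALSE
"sym_vomiting","health",0,1,"","0.96;0.04","0.10;0.00;0.05;0.05;0.80",0.6,FALSE,FALSE,FALSE,FALSE,FALSE
"sym_dehydration","health",0,1,"","0.97;0.03","0.10;0.00;0.05;0.05;0.80",0.6,FALSE,FALSE,FALSE,FALSE,FALSE
"sym_insufficient_fluid","health",0,1,"","0.95;0.05","0.10;0.00;0.05;0.05;0.80",0.6,FALSE,FALSE,FALSE,FALSE,FALSE
"sym_weight_loss","health",0,1,"","0.92;0.08","0.10;0.00;0.05;0.05;0.80",0.6,FALSE,FALSE,FALSE,FALSE,FALSE
"sym_dyspnea","health",0,1,"","0.85;0.15","0.10;0.00;0.05;0.05;0.80",0.6,FALSE,FALSE,FALSE,FALSE,FALSE
"sym_edema","health",0,1,"","0.82;0.18","0.10;0.00;0.05;0.05;0.80",0.6,FALSE,FALSE,FALSE,FALSE,FALSE
"decline_decision","health",0,1,"","0.85;0.15","0.3;0.2;0.0;0.0;0.7",0.6,FALSE,FALSE,FALSE,FALSE,FALSE
"decline_adl","health",0,1,"","0.85;0.15","0.3;0.2;0.0;0.0;0.7",0.6,FALSE,FALSE,FALSE,FALSE,FALSE
"end_stage_disease","health",0,1,"","0.99;0.01","0.10;0.00;0.00;0.05;0.80",0.6,FALSE,FALSE,FALSE,FALSE,FALSE
"beh_wandering","behaviour",0,1,"","0.97;0.03","0.0;0.8;0.0;0.0;0.1",0.6,FALSE,FALSE,FALSE,FALSE,FALSE
"beh_behaviour_symptoms","behaviour",0,1,"","0.94;0.06","0.0;0.7;0.3;0.0;0.0",0.6,FALSE,FALSE,FALSE,FALSE,FALSE
"falls","health",0,1,"","0.7;0.3","0.4;0.2;0.0;0.1;0.4",0.75,FALSE,FALSE,FALSE,FALSE,FALSE
"env_hazard","environment",0,1,"","0.9;0.1","0.3;0.3;0.1;0.0;0.1",0.9,FALSE,FALSE,FALSE,FALSE,FALSE
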