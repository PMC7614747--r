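tissue,freq_MHz,eps_r,sigma_S_per_m,rho_kg_m3,k_W_m_K,c_J_kg_K,perfusion_ml_min_kg,qmet_W_kg,source
skin,297,49.9,0.64,1109,0.37,3391,106,1.65,literature-representative adult value (IT'IS-style database)
fat,297,11.7,0.077,911,0.21,2348,33,0.51,literature-representative adult value (IT'IS-style database)
muscle,297,58.2,0.77,1090,0.49,3421,37,0.91,literature-representative adult value (IT'IS-style database)
bone,297,13.4,0.083,1908,0.32,1313,10,0.15,literature-representative adult value (IT'IS-style database)
brain,297,60.0,0.69,1045,0.55,3696,764,15.5,literature-representative adult value (grey matter; IT'IS-style database)
csf,297,72.7,2.22,1007,0.57,4096,0,0,literature-representative adult value (IT'IS-style database)
blood,297,65.7,1.32,1050,0.52,3617,2000,0,chamber/vessel blood; strong coupling to blood pool via perfusion term
heart,297,63.9,0.91,1081,0.56,3686,1026,39.5,literature-representative adult value (IT'IS-style database)
lung,297,23.6,0.34,394,0.39,3886,401,0,literature-representative adult value (inflated; IT'IS-style database)
liver,297,50.8,0.65,1079,0.52,3540,860,33.1,literature-representative adult value (IT'IS-style database)
cartilage,297,43.8,0.52,1100,0.49,3568,35,0.54,literature-representative adult value (IT'IS-style database)
connective,297,47.0,0.56,1027,0.39,2372,37,0.58,literature-representative adult value (IT'IS-style database)
eye,297,69.0,1.52,1005,0.59,4047,0,0,literature-representative adult value (vitreous humour; IT'IS-style database)
blanket_wool,297,1.2,0,150,0.04,1360,0,0,wool felt insulation layer; not a tissue (zero perfusion and metabolism)
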