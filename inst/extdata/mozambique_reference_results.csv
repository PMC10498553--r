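perspective,strategy,total_cost,dalys_averted,survival_years,years_on_art,annual_cost_on_art
patient,clinical_6m,24.15,10.79,24.6,16.9,2.16
patient,mixed_6m_community_3m,25.29,11.21,25.9,19.2,2.08
patient,community_3m,26.82,11.74,27.6,22.5,2.01
patient,clinical_3m,33.49,9.86,21.9,12.2,3.72
patient,clinical_3m_case_mgmt,47.03,11.92,28.5,20.7,3.69
patient,clinical_1m,77.92,9.37,20.5,10.3,9.83
health_sector,clinical_3m,1284,9.87,21.9,12.2,142
health_sector,clinical_6m,1405,10.80,24.6,16.8,125
health_sector,clinical_1m,1548,9.39,20.6,10.4,195
health_sector,mixed_6m_community_3m,2073,11.22,25.9,19.2,170
health_sector,community_3m,2905,11.74,27.6,22.5,218
health_sector,clinical_3m_case_mgmt,6203,11.93,28.5,20.8,486
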