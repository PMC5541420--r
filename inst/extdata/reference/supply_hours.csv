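stratum,cadre,n,total_as,total_is_tu,total_is_tr,median_as,median_is_tu,median_is_tr,wilcoxon_p_tu,wilcoxon_p_tr,friedman_p
urban,physician,12,141600,373462.6,562069.7,12000,22624.2,35876.9,0.0029,0.0022,0.0013
urban,nurse,12,220800,231150.6,332150.6,17400,12654.8,21913.9,0.2094,0.0995,0.0012
urban,health_promoter,12,27600,243449.9,406915.0,0,16749.0,32658.9,0.0022,0.0022,0.0280
rural,physician,8,30000,628853.6,84632.2,1800,4079.7,5460.1,0.0499,0.0173,0.0262
rural,nurse,8,38400,40127.2,57173.1,1200,2173.6,3182.4,NA,NA,0.0837
rural,health_promoter,8,1200,35627.8,52308.2,0,2151.3,3714.2,NA,NA,0.1705
total,physician,20,171600,436316.2,646701.9,6000,12478.5,16510.6,0.0004,0.0001,0.0000
total,nurse,20,259200,271545.6,389393.7,10800,7904.6,11321.3,0.2627,0.0187,0.0001
total,health_promoter,20,28800,279077.7,459223.2,0,7220.7,9252.0,0.0001,0.0001,0.0167
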