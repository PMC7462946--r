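patient,metric,artery,roi_id,pre_value,post_value,rise_printed
1,MTT,ATA,1,5.89,5.20,-10.81
1,MTT,PA,2,4.58,10.21,123.10
1,MTT,PA,3,8.19,8.52,4.10
1,MTT,PA,4,8.05,8.78,9.05
2,MTT,ATA,1,17.25,5.77,-66.56
2,MTT,PA,2,15.76,7.27,-66.56
2,MTT,PA,3,16.01,10.85,-66.56
2,MTT,PA,4,19.00,11.79,-66.56
3,MTT,ATA,1,12.71,4.56,-64.16
3,MTT,PA,2,13.14,11.66,-11.23
3,MTT,PA,3,15.75,10.29,-34.68
4,MTT,ATA,1,12.43,8.83,-28.98
4,MTT,PA,2,13.28,8.38,-36.92
5,MTT,ATA,1,13.09,5.35,-59.15
5,MTT,PA,2,14.56,5.57,-61.72
1,PBF,ATA,1,0.04,0.14,232.26
1,PBF,PA,2,0.11,0.08,-26.39
1,PBF,PA,3,0.05,0.12,131.10
1,PBF,PA,4,0.05,0.09,79.47
2,PBF,ATA,1,0.015,0.08,404.57
2,PBF,PA,2,0.021,0.04,220.93
2,PBF,PA,3,0.024,0.08,233.61
2,PBF,PA,4,0.00,0.06,1453.85
3,PBF,ATA,1,0.03,0.19,3360.29
3,PBF,PA,2,0.02,0.03,39.09
3,PBF,PA,3,0.02,0.09,290.00
4,PBF,ATA,1,0.04,0.05,18.59
4,PBF,PA,2,0.04,0.03,-23.76
5,PBF,ATA,1,0.04,0.09,140.53
5,PBF,PA,2,0.03,0.07,135.78
1,PBV,ATA,1,0.20,0.39,96.22
1,PBV,PA,2,0.49,0.29,-40.58
1,PBV,PA,3,0.26,0.38,43.35
1,PBV,PA,4,0.24,0.29,19.11
2,PBV,ATA,1,0.22,0.39,75.52
2,PBV,PA,2,0.17,0.24,39.80
2,PBV,PA,3,0.36,0.41,14.07
2,PBV,PA,4,0.07,0.47,529.45
3,PBV,ATA,1,0.37,0.86,131.05
3,PBV,PA,2,0.18,0.16,-11.02
3,PBV,PA,3,0.27,0.53,95.39
4,PBV,ATA,1,0.41,0.41,0.02
4,PBV,PA,2,0.38,0.23,-41.28
5,PBV,ATA,1,0.28,0.45,59.53
5,PBV,PA,2,0.28,0.37,34.07
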