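species,ad_m,fid_m,slope_s,intercept_m,body_mass_g
synthetic_sp_01,63.7,25.17,-3.94,-8.13,11.5
synthetic_sp_02,34.86,70.41,2.47,37.6,13.1
synthetic_sp_03,46.56,93.37,4.48,105.47,14.9
synthetic_sp_04,52.45,97.03,-0.34,-10.76,16.9
synthetic_sp_05,55.36,65.51,-13.41,38.84,19.2
synthetic_sp_06,52.5,26.21,2.05,78.99,21.9
synthetic_sp_07,42.34,5.55,-11.16,40.69,24.9
synthetic_sp_08,54.49,29.25,-4.07,77.5,28.3
synthetic_sp_09,61.23,54.86,-3.38,112.82,32.1
synthetic_sp_10,52.31,56.36,-6.57,-24.63,36.5
synthetic_sp_11,51.17,55.68,-6.2,-35.56,41.5
synthetic_sp_12,55.26,7.49,32.33,111.64,47.2
synthetic_sp_13,41.14,7.73,-17.02,-25.14,53.7
synthetic_sp_14,50.1,13.67,-8.11,64.39,61.1
synthetic_sp_15,56.02,8.98,2.03,18.78,69.4
synthetic_sp_16,61.23,20.08,6.29,128.4,79
synthetic_sp_17,40.39,46.5,7.85,63.78,89.8
synthetic_sp_18,56.91,74.67,-9.46,-14.2,102.1
synthetic_sp_19,9.9,70.12,6.39,44.56,116.1
synthetic_sp_20,35.44,98.92,-9.81,33.08,132
synthetic_sp_21,43.46,22.55,-9.11,56.38,150.1
synthetic_sp_22,49.08,17.69,16.13,65.53,170.6
synthetic_sp_23,48.47,13.12,-14.29,99.33,194
synthetic_sp_24,60.4,65.13,8.45,97.04,220.6
synthetic_sp_25,58.66,72.27,13.35,98.38,250.8
synthetic_sp_26,60.72,23.24,-19.88,52,285.2
synthetic_sp_27,61.23,45.32,3.19,10.21,324.3
synthetic_sp_28,56.09,26.86,8.98,20.83,368.7
synthetic_sp_29,47.3,46.09,-3.32,27.88,419.2
synthetic_sp_30,53.56,62.82,-3.65,23.89,476.7
synthetic_sp_31,61.23,7.49,-19.4,42.9,542
synthetic_sp_32,47.88,67.63,10.64,97.44,616.3
synthetic_sp_33,61.23,29.13,-2.23,-0.45,700.8
synthetic_sp_34,49.67,35.01,1.96,111,796.8
synthetic_sp_35,61.23,15.33,2.53,45.14,906
synthetic_sp_36,43.15,7.56,4.07,75.18,1030.2
synthetic_sp_37,61.23,45.62,5.32,36.53,1171.3
synthetic_sp_38,51.67,7.49,5.18,-33.15,1331.9
synthetic_sp_39,39.66,22.01,-11.15,27.07,1514.4
synthetic_sp_40,29.48,83.29,2.88,122.36,1721.9
synthetic_sp_41,45.42,32.86,1.23,64.72,1957.9
synthetic_sp_42,46.22,37.25,-9.46,56.71,2226.2
synthetic_sp_43,38.87,75.96,0.88,65.96,2531.3
synthetic_sp_44,44.65,24.28,-7.94,-75.7,2878.2
synthetic_sp_45,43.35,69.42,-11.69,-2.34,3272.7
synthetic_sp_46,61.23,101.95,-13.84,0.97,3721.2
synthetic_sp_47,43.1,128.38,-37.46,55.14,4231.1
synthetic_sp_48,32.15,70.46,1.26,16.37,4811
synthetic_sp_49,42.4,7.49,-2.15,10.14,5470.3
synthetic_sp_50,61.23,7.49,3.12,43.25,6220
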