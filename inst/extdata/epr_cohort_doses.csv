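mouse_id,side,dose_Gy,sigma_Gy,missing
Mouse_01,right,189.2,10.2,FALSE
Mouse_01,left,228.4,20.5,FALSE
Mouse_02,right,179.6,6.7,FALSE
Mouse_02,left,184.8,12.5,FALSE
Mouse_03,right,171.1,17.5,FALSE
Mouse_03,left,224.8,19.7,FALSE
Mouse_04,right,166.5,10.2,FALSE
Mouse_04,left,186.6,10.3,FALSE
Mouse_05,right,262.5,26.8,FALSE
Mouse_05,left,247.8,15.1,FALSE
Mouse_06,right,156.3,15.0,FALSE
Mouse_06,left,183.9,7.8,FALSE
Mouse_07,right,163.5,7.6,FALSE
Mouse_07,left,223.6,9.5,FALSE
Mouse_08,right,182.1,11.0,FALSE
Mouse_08,left,162.9,11.1,FALSE
Mouse_09,right,189.2,8.8,FALSE
Mouse_09,left,188.2,8.2,FALSE
Mouse_10,right,226.7,16.8,FALSE
Mouse_10,left,221.5,18.7,FALSE
Mouse_11,right,183.4,13.9,FALSE
Mouse_11,left,198.0,17.1,FALSE
Mouse_12,right,182.9,8.8,FALSE
Mouse_12,left,218.7,4.9,FALSE
Mouse_13,right,164.6,7.4,FALSE
Mouse_13,left,166.0,9.7,FALSE
Mouse_14,right,182.0,17.1,FALSE
Mouse_14,left,NA,NA,TRUE
Mouse_15,right,198.1,9.8,FALSE
Mouse_15,left,193.9,13.5,FALSE
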