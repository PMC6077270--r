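sample_id,channel,compartment,k,counts,circle_area_mm2,mean_density
ctrl_01,edu,proliferating,3,15;17;9,0.0271072,504.171093534805
ctrl_01,protein,proliferating,3,14;12;8,0.0271072,418.093101955692
ctrl_02,edu,proliferating,3,13;14;9,0.0227792,526.796375640936
ctrl_02,protein,proliferating,3,11;10;11,0.0227792,468.263445014165
trt_01,edu,proliferating,3,15;14;16,0.0353088,424.823273518216
trt_01,protein,proliferating,3,11;6;7,0.0353088,226.572412543049
trt_02,edu,proliferating,3,4;3;3,0.01968,169.376693766938
trt_02,protein,proliferating,3,4;6;3,0.01968,220.189701897019
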