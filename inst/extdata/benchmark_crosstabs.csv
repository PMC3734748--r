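method_a,method_b,row_label,low,normal,high,kappa_printed
fixed_ramr,fixed_rank,low,20,0,0,0.71
fixed_ramr,fixed_rank,normal,7,88,0,0.71
fixed_ramr,fixed_rank,high,0,9,4,0.71
fixed_ramr,hier_ramr,low,6,14,0,0.46
fixed_ramr,hier_ramr,normal,0,95,0,0.46
fixed_ramr,hier_ramr,high,0,8,5,0.46
fixed_rank,hier_ramr,low,6,21,0,0.44
fixed_rank,hier_ramr,normal,0,96,1,0.44
fixed_rank,hier_ramr,high,0,0,4,0.44
hier_rank,fixed_ramr,low,2,0,0,0.32
hier_rank,fixed_ramr,normal,18,95,8,0.32
hier_rank,fixed_ramr,high,0,0,5,0.32
hier_rank,fixed_rank,low,2,0,0,0.29
hier_rank,fixed_rank,normal,25,96,0,0.29
hier_rank,fixed_rank,high,0,1,4,0.29
hier_rank,hier_ramr,low,2,0,0,0.77
hier_rank,hier_ramr,normal,4,117,0,0.77
hier_rank,hier_ramr,high,0,0,5,0.77
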