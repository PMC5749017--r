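quantity,value
cohort_total,8815
total_visits,110794
rourke_any,7051
rourke_none,1764
auto_classified,4955
manual_classified,2816
feeding_undetermined,1044
complete_case_n,3959
kappa_inter_rater,0.936
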