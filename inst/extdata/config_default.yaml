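vaf_germline_cut: 0.97
popdb_cut: 0.01
pon_cut: 0.03
pon_n: 480
loss_below: 1.0
gain_above: 4.0
fish_fold_threshold: 10.0
survival_horizon_months: 36.0
strand_bias_p: 0.001
strand_bias_fraction: 0.95
cluster_window_bp: 10
cluster_min_calls: 3
min_callers: 1
purity_grid:
- 0.05
- 0.06
- 0.07
- 0.08
- 0.09
- 0.1
- 0.11
- 0.12
- 0.13
- 0.14
- 0.15
- 0.16
- 0.17
- 0.18
- 0.19
- 0.2
- 0.21
- 0.22
- 0.23
- 0.24
- 0.25
- 0.26
- 0.27
- 0.28
- 0.29
- 0.3
- 0.31
- 0.32
- 0.33
- 0.34
- 0.35
- 0.36
- 0.37
- 0.38
- 0.39
- 0.4
- 0.41
- 0.42
- 0.43
- 0.44
- 0.45
- 0.46
- 0.47
- 0.48
- 0.49
- 0.5
- 0.51
- 0.52
- 0.53
- 0.54
- 0.55
- 0.56
- 0.57
- 0.58
- 0.59
- 0.6
- 0.61
- 0.62
- 0.63
- 0.64
- 0.65
- 0.66
- 0.67
- 0.68
- 0.69
- 0.7
- 0.71
- 0.72
- 0.73
- 0.74
- 0.75
- 0.76
- 0.77
- 0.78
- 0.79
- 0.8
- 0.81
- 0.82
- 0.83
- 0.84
- 0.85
- 0.86
- 0.87
- 0.88
- 0.89
- 0.9
- 0.91
- 0.92
- 0.93
- 0.94
- 0.95
- 0.96
- 0.97
- 0.98
- 0.99
- 1.0
cn_max: 10
seed: 1
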