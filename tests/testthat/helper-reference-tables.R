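# Per-subject reference values from the 12-subject overnight validation
# study this package models (7 normal sleepers, 2 obstructive sleep apnea,
# 3 periodic limb movement disorder), used to check that the metric and
# aggregation operations reproduce the published summary arithmetic.

# epoch-by-epoch statistics per subject and estimator
ref_subject_stats <- read.csv(text = "subject,group,method,sens,spec,ppv,npv,accu,kappa,f
1,N,TDA,0.99,0.69,0.56,1.00,0.78,0.64,0.72
1,N,FDA,1.00,0.71,0.60,1.00,0.80,0.69,0.75
2,N,TDA,0.99,0.74,0.65,0.99,0.82,0.64,0.79
2,N,FDA,0.99,0.73,0.63,0.99,0.81,0.67,0.77
3,N,TDA,1.00,0.70,0.58,1.00,0.79,0.70,0.73
3,N,FDA,0.99,0.71,0.59,1.00,0.79,0.67,0.74
4,N,TDA,0.98,0.75,0.68,0.98,0.83,0.61,0.80
4,N,FDA,0.98,0.71,0.60,0.99,0.79,0.59,0.74
5,N,TDA,0.99,0.69,0.56,0.99,0.77,0.61,0.71
5,N,FDA,0.99,0.80,0.73,0.99,0.82,0.72,0.99
6,N,TDA,0.99,0.78,0.71,0.99,0.85,0.73,0.83
6,N,FDA,0.99,0.77,0.71,0.99,0.85,0.67,0.82
7,N,TDA,0.99,0.65,0.47,1.00,0.73,0.55,0.63
7,N,FDA,1.00,0.70,0.57,1.00,0.78,0.66,0.73
8,O,TDA,0.99,0.71,0.59,0.99,0.79,0.64,0.74
8,O,FDA,0.99,0.77,0.71,0.99,0.85,0.68,0.82
9,O,TDA,1.00,0.68,0.53,1.00,0.76,0.64,0.69
9,O,FDA,0.99,0.75,0.67,1.00,0.83,0.66,0.80
10,P,TDA,0.95,0.63,0.44,0.98,0.71,0.47,0.60
10,P,FDA,0.94,0.70,0.58,0.96,0.77,0.40,0.72
11,P,TDA,0.99,0.59,0.31,1.00,0.66,0.44,0.48
11,P,FDA,0.99,0.67,0.52,0.99,0.76,0.56,0.68
12,P,TDA,0.96,0.55,0.19,0.99,0.59,0.26,0.32
12,P,FDA,0.98,0.60,0.34,0.99,0.67,0.41,0.51",
stringsAsFactors = FALSE)

# published mean (SD) summary rows for the statistics table, at the printed
# 2-dp rounding, per subject group
ref_summary_rows <- read.csv(text = "group,method,sens_m,sens_sd,spec_m,spec_sd,ppv_m,ppv_sd,npv_m,npv_sd,accu_m,accu_sd,kappa_m,kappa_sd,f_m,f_sd
N,TDA,0.99,0.01,0.71,0.04,0.60,0.08,0.99,0.01,0.80,0.04,0.64,0.06,0.74,0.07
N,FDA,0.99,0.01,0.73,0.04,0.63,0.06,0.99,0.01,0.81,0.02,0.67,0.04,0.79,0.09
NO,TDA,0.99,0.01,0.71,0.04,0.59,0.08,0.99,0.01,0.79,0.04,0.64,0.05,0.74,0.06
NO,FDA,0.99,0.01,0.74,0.04,0.65,0.06,0.99,0.01,0.81,0.03,0.67,0.03,0.80,0.08
NOP,TDA,0.99,0.02,0.68,0.07,0.52,0.15,0.99,0.01,0.76,0.07,0.58,0.13,0.67,0.15
NOP,FDA,0.99,0.02,0.72,0.05,0.60,0.11,0.99,0.01,0.79,0.05,0.62,0.11,0.76,0.11",
stringsAsFactors = FALSE)

# sleep-efficiency comparison (PSG reference vs frequency-domain estimate)
ref_sleep_eff <- read.csv(text = "subject,se_psg,se_est,abs_d,rel_d
1,98.2,97.5,0.7,0.7
2,97.3,96.9,0.4,0.4
3,97.8,97.0,0.9,0.9
4,96.3,96.3,0.0,0.0
5,97.2,98.4,1.2,1.3
6,97.4,97.6,0.2,0.2
7,98.9,98.5,0.4,0.4
8,98.1,98.2,0.1,0.1
9,98.8,97.8,0.9,1.0
10,94.1,96.6,2.5,2.7
11,97.9,97.5,0.5,0.5
12,98.2,97.0,1.2,1.2", stringsAsFactors = FALSE)

# posture-stratified epoch counts and kappa (time-domain estimator); NA
# where a subject never took the posture
ref_posture <- list(
  epochs = data.frame(
    supine = c(627, 756, 681, 756, 687, 959, 849, 592, 863, 641, 565, 900),
    left   = c(173, 0, 137, 0, 277, 0, 0, 0, 0, 155, 336, 79),
    right  = c(177, 81, 122, 81, 0, 44, 0, 383, 110, 151, 0, 0),
    prone  = rep(0, 12)),
  kappa = data.frame(
    supine = c(.68, .63, .72, .60, .56, .71, .55, .63, .66, .42, .56, .25),
    left   = c(.60, NA, .69, NA, .70, NA, NA, NA, NA, .51, .38, .46),
    right  = c(.52, .65, .61, .65, NA, .76, NA, .64, .61, .46, NA, NA),
    prone  = rep(NA_real_, 12)),
  # published summary: mean (SD) of epochs over all subjects (absent
  # postures as 0) and of kappa over subjects who took the posture
  summary = data.frame(
    posture = c("supine", "left", "right"),
    epochs_m = c(739.6, 96.4, 95.8), epochs_sd = c(128.8, 119.5, 109.9),
    kappa_m = c(0.58, 0.56, 0.61), kappa_sd = c(0.13, 0.13, 0.09)))

# round half away from zero at the table's printed precision (plain
# round() is banker's rounding, which 2-dp table values like 0.565 defeat)
round_printed <- function(x, digits) round(x + sign(x) * 1e-9, digits)
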