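# Default ratvar pipeline configuration.
# Group parameters calibrate the synthetic 2x2 cohort (diabetes x renal
# denervation in the spontaneously hypertensive rat) to published group
# means/SDs for this model; beat-series oscillation amplitudes are set so
# that sinusoid power (amp^2/2) reproduces the target LF/HF absolute
# powers and white noise tops up the target total variability.

sampling_rate: 2000        # Hz, arterial-pressure waveform
alpha: 0.05                # significance level
dispersion_label: sd       # label used in reports: sd or sem
albumin_interval: range    # interpretation of albumin brackets: range | iqr

fragment:
  target_len: 300          # beats per stationary fragment
  k_mean: 0.5              # thirds-mean stationarity threshold (x window SD)
  k_var: 1.0               # thirds-variance threshold (x window variance)

ar:
  p_min: 8                 # AIC order-selection range
  p_max: 20

bands:                     # Hz; rat conventions
  vlf_lo: 0.0
  lf_lo: 0.2
  hf_lo: 0.75
  hf_hi: 3.0

inclusion:
  glycemia_threshold: 300  # mg/dL, strict inequality, diabetic groups only

n_beats: 1200              # beats simulated per animal

groups:
  - label: SHR
    diabetes: false
    denervation: false
    n_animals: 7
    outcomes:
      weight_initial:   {mean: 258,   sd: 14}
      weight_45d:       {mean: 310,   sd: 28}
      glycemia_initial: {mean: 84.4,  sd: 7}
      glycemia_45d:     {mean: 92.0,  sd: 14}
      diuresis:         {mean: 11.2,  sd: 4}
      urinary_glucose:  {mean: 0.37,  sd: 0.4}
      urinary_sodium:   {mean: 1.03,  sd: 0.3}
      densitometry:     {mean: 100,   sd: 14}
    albumin: {median: 152, lo: 111, hi: 341}
    beats:
      hr:  {mean: 384.82, sd: 37.26}
      sap: {mean: 178.43, sd: 16.07}
      dap: {mean: 141.17, sd: 19.10}
      lf_freq: 0.45
      hf_freq: 2.0
      pi_lf_amp: 3.22      # sqrt(2 * 5.17)
      pi_hf_amp: 5.40      # sqrt(2 * 14.56)
      pi_noise_sd: 7.08
      sap_lf_amp: 6.08
      sap_hf_amp: 3.06
      sap_noise_sd: 6.72
  - label: RD-SHR
    diabetes: false
    denervation: true
    n_animals: 6
    outcomes:
      weight_initial:   {mean: 267,   sd: 29}
      weight_45d:       {mean: 322,   sd: 35}
      glycemia_initial: {mean: 91.2,  sd: 5}
      glycemia_45d:     {mean: 91.1,  sd: 9}
      diuresis:         {mean: 20.7,  sd: 7}
      urinary_glucose:  {mean: 0.23,  sd: 0.4}
      urinary_sodium:   {mean: 1.29,  sd: 0.8}
      densitometry:     {mean: 185.6, sd: 13}
    albumin: {median: 711, lo: 273, hi: 1304}
    beats:
      hr:  {mean: 431.32, sd: 36.60}
      sap: {mean: 171.03, sd: 5.22}
      dap: {mean: 150.27, sd: 13.52}
      lf_freq: 0.45
      hf_freq: 2.0
      pi_lf_amp: 1.80      # sqrt(2 * 1.62)
      pi_hf_amp: 2.88      # sqrt(2 * 4.14)
      pi_noise_sd: 7.07
      sap_lf_amp: 2.72
      sap_hf_amp: 10.39
      sap_noise_sd: 2.06
  - label: STZ-SHR
    diabetes: true
    denervation: false
    n_animals: 6
    outcomes:
      weight_initial:   {mean: 269,   sd: 13}
      weight_45d:       {mean: 275,   sd: 53}
      glycemia_initial: {mean: 414.1, sd: 135}
      glycemia_45d:     {mean: 417.5, sd: 114}
      diuresis:         {mean: 96.9,  sd: 42}
      urinary_glucose:  {mean: 758.0, sd: 544}
      urinary_sodium:   {mean: 4.38,  sd: 2.1}
      densitometry:     {mean: 182.7, sd: 21}
    albumin: {median: 2456, lo: 1491, hi: 3982}
    beats:
      hr:  {mean: 316.21, sd: 5.17}
      sap: {mean: 145.39, sd: 8.49}
      dap: {mean: 116.26, sd: 29.34}
      lf_freq: 0.45
      hf_freq: 2.0
      pi_lf_amp: 2.06      # sqrt(2 * 2.12)
      pi_hf_amp: 8.01      # sqrt(2 * 32.11)
      pi_noise_sd: 6.26
      sap_lf_amp: 1.66
      sap_hf_amp: 3.36
      sap_noise_sd: 2.93
  - label: RD-STZ-SHR
    diabetes: true
    denervation: true
    n_animals: 5
    outcomes:
      weight_initial:   {mean: 272,   sd: 28}
      weight_45d:       {mean: 223,   sd: 71}
      glycemia_initial: {mean: 357.4, sd: 124}
      glycemia_45d:     {mean: 388.0, sd: 48}
      diuresis:         {mean: 103.3, sd: 38}
      urinary_glucose:  {mean: 1019.0, sd: 379}
      urinary_sodium:   {mean: 4.50,  sd: 1.8}
      densitometry:     {mean: 201.4, sd: 25}
    albumin: {median: 1538, lo: 667, hi: 2988}
    beats:
      hr:  {mean: 363.81, sd: 12.25}
      sap: {mean: 157.20, sd: 26.41}
      dap: {mean: 118.88, sd: 10.75}
      lf_freq: 0.45
      hf_freq: 2.0
      pi_lf_amp: 3.84      # sqrt(2 * 7.38)
      pi_hf_amp: 8.63      # sqrt(2 * 37.22)
      pi_noise_sd: 10.19
      sap_lf_amp: 10.64
      sap_hf_amp: 3.54
      sap_noise_sd: 1.0    # floored; see vignette on group variance targets
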