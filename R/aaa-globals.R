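## package-wide constants (this file collates first)

.sources <- c("billing", "encounter_diagnosis", "health_condition",
              "medication", "referral")
.diag_sources <- c("billing", "encounter_diagnosis", "health_condition")

.variants <- c("ge1_whole_chart", "ge2_12mo", "ge2_24mo", "ge2_whole_chart")

## days per rolling window; "12/24 consecutive months" is implemented as a
## rolling 365/730-day window, which is monotone and order-free
.window_days <- c("12" = 365, "24" = 730)

.text_scope_string <- paste(.sources, collapse = "+")
.diag_scope_string <- paste(.diag_sources, collapse = "+")
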