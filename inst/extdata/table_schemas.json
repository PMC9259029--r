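{
  "trial": ["time_s", "theta_thorax_deg", "theta_head_thorax_deg"],
  "metrics": ["trial_id", "animal_id", "treatment", "light", "frequency",
              "gain", "phase_xcorr_deg", "phase_fft_deg", "epsilon",
              "coherence", "flags"],
  "summaries": ["treatment", "light", "frequency", "n", "median_gain",
                "circ_median_phase_deg", "median_epsilon", "sem_epsilon"],
  "stats": ["comparison", "test", "statistic", "p", "n"]
}
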