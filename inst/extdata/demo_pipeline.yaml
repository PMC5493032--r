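# Demo pipeline configuration: simulated 8 s EEG with a large (400 uV) EOG
# pulse train, baseline drift and noise, denoised and classified by
# adaptive SSA. Run with:
#   run_pipeline(system.file("extdata", "demo_pipeline.yaml",
#                            package = "eegssa"),
#                out_dir = "demo_out", seed = 1)
simulate:
  duration: 8
  dt: 0.005
  v_eog: 400
  t_eog: 3
  pw_eog: 0.3
  v_bl: 20
  f_bl: 0.5
  noise_sd: 2
window: 40
v0: 200
tol: 0.05
band: alpha
threshold: 10
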