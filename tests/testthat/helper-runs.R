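# memoised scenario runs shared between test files (several acceptance and
# property checks interrogate the same simulated histories)
.run_cache <- new.env(parent = emptyenv())

run_memo <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

csi_history <- function(test, law, phi0 = 1) {
  run_memo(paste("csi", test, law, phi0, sep = "_"),
           run_csi_test(test = test, cfg = csi_config(law = law, phi0 = phi0)))
}

# small, fast ACI used by property checks (coarser than the default study mesh)
aci_small_cfg <- function(...) {
  aci_config(mesh_scale = 0.55, du_insert = 100e-6, n_removal = 40, ...)
}

table3_params <- function(law = "emc") {
  adhesive_friction_params(
    a_s = 22e-6, b_s = 0.74, mu_ub = 0.44, mu_b = 0.3,
    t0 = if (law == "emc") 1.8e6 else 0, g0 = 66e-6, g_b = 66e-6,
    eps_n = 18e9 / 0.01, eps_t = 18e9 / 0.01, law = law
  )
}
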