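# Shared, lazily computed fixtures. Solves are deterministic, so each
# expensive continuation is run once per test session and reused across
# files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) assign(name, fn(), envir = .fixtures)
  .fixtures[[name]]
}

tab1_params <- function() model_parameters()

cfg_unit <- function(mesh = 601) solver_config(mesh_size = mesh,
                                               step_halving_limit = 4)
cfg_acc <- function() solver_config(mesh_size = 801, step_halving_limit = 5)

# Protein-density continuation 0 -> 1.25e-4 on the centred 8-um domain
fig3_branch <- function() fixture("fig3", function() {
  pars <- tab1_params()
  continuation(seq(0, 1.25e-4, length.out = 26), function(v)
    list(fields = single_domain_profiles(pars, v, 1), params = pars),
    config = cfg_acc(), param_name = "sigma0")
})

# Rigidity-ratio continuation 1 -> 30 at constant density, C = 0
fig4_sweep <- function() fixture("fig4", function() {
  run_rigidity_sweep(tab1_params(), sigma0 = 1.25e-4, kappa_ratio_max = 30,
                     n_steps = 15, config = cfg_acc())
})

# Small-deformation branch 0 -> 2.5e-5 (uniform rigidity)
small_branch <- function() fixture("small", function() {
  pars <- tab1_params()
  continuation(seq(0, 2.5e-5, length.out = 6), function(v)
    list(fields = single_domain_profiles(pars, v, 1), params = pars),
    config = cfg_unit(), param_name = "sigma0")
})

homog_tube <- function() fixture("homog", function() {
  pars <- tab1_params()
  solve_shape(homogeneous_profiles(pars), pars,
              config = solver_config(mesh_size = 401))
})

validation_report <- function() fixture("validation", function() {
  run_validation_suite(tab1_params(), config = solver_config(mesh_size = 601))
})

# An asymmetric (off-centre) protein domain, for symmetry-mode checks
make_off_center_profiles <- function(pars) {
  nanobead:::make_profile_set(
    pars,
    list(domain_spec(pars$Lc / 3, 4000, 1e-5, 350)),
    list(), list(), nanobead:::default_kappaG(pars), 1001)
}

# Rigidity-only two-domain merge sweep (C = 0, kappa_ratio = 11)
t3_study <- function() fixture("t3", function() {
  merge_study(model_parameters(phi = 0), sigma0 = 1.25e-4,
              kappa_ratio = 11, L_domain = 8000,
              separations = seq(0, 4000, length.out = 21),
              direction = "both", config = cfg_acc())
})
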