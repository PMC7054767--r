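# YAML run configuration: geometry fixture (or external mesh), fluid and
# forcing constants, outlet assignment, numerical settings, probe geometry
# and an optional experiment block.  Every field has the package default,
# so a minimal file like "geometry: {fixture: channel}" is complete.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from YAML
#'
#' Builds the domain and [simulation_config()] described by a YAML file
#' with sections `geometry` (fixture `coronary_tree` or `channel` with
#' their parameters, element size `h`, or `mesh_file` pointing to a Gmsh
#' MSH file), `fluid`, `forcing`, `outlets`, `simulation`, `ffr`, and
#' optionally `experiment` (`kind`: `run`, `converge`, `grid`, `sweep` or
#' `fields`, plus its parameters).
#'
#' @param path YAML file path.
#' @return List with `domain` (or `mesh` for external meshes), `h`,
#'   `config` (a [simulation_config()]) and `experiment` (a named list or
#'   `NULL`).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  g <- y$geometry %||% list()
  h <- g$h %||% 0.1
  m <- NULL
  domain <- NULL
  if (!is.null(g$mesh_file)) {
    m <- read_mesh(g$mesh_file)
  } else {
    fixture <- g$fixture %||% "coronary_tree"
    domain <- switch(fixture,
      coronary_tree = coronary_tree_domain(
        lesions = as.integer(g$lesions %||% c(1L, 2L)),
        sensors = g$sensors %||% TRUE),
      channel = do.call(channel_domain, g$channel %||% list(degree = 0.68)),
      stop("unknown geometry fixture: ", fixture))
  }

  fl <- y$fluid %||% list()
  cr <- fl$carreau %||% list()
  fluid <- fluid_params(
    rho = fl$rho %||% 1060,
    model = fl$model %||% "carreau",
    newtonian_mu = fl$newtonian_mu %||% 0.0032,
    carreau = carreau_params(mu0 = cr$mu0 %||% 0.0456,
                             mu_inf = cr$mu_inf %||% 0.0032,
                             lambda = cr$lambda %||% 10.03,
                             n = cr$n %||% 0.344))

  fo <- y$forcing %||% list()
  wf <- inlet_waveform(Ip = fo$Ip %||% 10, I0 = fo$I0 %||% 10,
                       Ic = fo$Ic %||% 10, Tsys = fo$Tsys %||% 0.33,
                       Tc = fo$Tc %||% 0.8)
  pd <- fo$pd %||% list()
  pd_flow <- aortic_flow_model(Q0 = pd$Q0 %||% 6, Tsys = wf$Tsys, Tc = wf$Tc)

  ou <- y$outlets %||% list()
  wk <- windkessel_params(R = ou$R %||% 0.95, C = ou$C %||% 1.06)
  kind <- ou$kind %||% "windkessel"
  if (length(kind) > 1L) kind <- as.character(unlist(kind))

  si <- y$simulation %||% list()
  fr <- y$ffr %||% list()
  config <- simulation_config(
    dt = si$dt %||% 5e-3,
    n_cycles = si$n_cycles %||% 5L,
    fluid = fluid, waveform = wf, wk = wk, pd_flow = pd_flow,
    pd_baseline = pd$baseline %||% 2,
    outlets = kind,
    inlet_mode = si$inlet_mode %||% "dirichlet_poiseuille",
    probe = probe_spec(arclength = fr$aortic_arclength %||% 1,
                       half_width = fr$box_half_width %||% 0.05),
    snapshots = si$snapshots %||% FALSE,
    seed = si$seed %||% 1L)

  list(domain = domain, mesh = m, h = h, config = config,
       experiment = y$experiment)
}
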