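# Configuration files and programmatic test fixtures.

#' Load a parameter configuration file
#'
#' Reads a flat YAML key-value file whose keys are exactly the
#' [soil_params()] field names, interpreted at the system size `k` given in
#' the same file (default 10). Keys absent from the file keep their default
#' values; unknown keys are an error. An empty file yields the defaults.
#'
#' @param path path to the YAML file; `NULL` loads the packaged default
#'   configuration.
#' @return a validated [soil_params()] object.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_params.yaml",
                        package = "decompevo", mustWork = TRUE)
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config file must be a flat key-value mapping")
  unknown <- setdiff(names(cfg), names(.unit_defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  k <- if (!is.null(cfg$k)) cfg$k else 10
  cfg$k <- NULL
  do.call(soil_params, c(list(k = k), cfg))
}

#' Apply `name=value` overrides to a parameter set
#'
#' Helper behind the command-line `--set` flag: each string is parsed as
#' `name=value` and assigned (numerically) over `params`.
#'
#' @param params a [soil_params()] object.
#' @param sets character vector of `name=value` strings.
#' @return the validated, updated parameter set.
#' @export
apply_overrides <- function(params, sets) {
  for (s in sets) {
    kv <- strsplit(s, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("override must be name=value: ", s)
    name <- trimws(kv[1])
    if (!name %in% names(.unit_defaults)) stop("unknown parameter: ", name)
    params[[name]] <- as.numeric(kv[2])
  }
  validate_params(params)
}

#' Deterministic generator of test lattices
#'
#' @param kind one of `"empty"` (no cells, zero pools), `"steady-monomorphic"`
#'   (every site at the deterministic equilibrium for `phi`, with the implied
#'   cell number and reserves drawn uniformly on `[0, omega_M)`),
#'   `"doc-spike"` (all DOC concentrated in one site, no cells) or
#'   `"two-strain-split"` (steady-state sites, left half of the columns
#'   strain 1 at `phi`, right half strain 2 at `phi2`).
#' @param params a [soil_params()] object.
#' @param phi trait value for populated fixtures.
#' @param phi2 second trait value for `"two-strain-split"`.
#' @param doc_total total DOC mass (mg) for `"doc-spike"`.
#' @param spike_site linear site index receiving the spike.
#' @return a [lattice_state()].
#' @export
make_fixture <- function(kind, params, phi = params$phi, phi2 = params$phi,
                         doc_total = params$K_m, spike_site = 1L) {
  L <- params$L
  lat <- lattice_state(params)
  switch(kind,
    "empty" = lat,
    "doc-spike" = {
      lat$d[spike_site] <- doc_total
      lat
    },
    "steady-monomorphic" = {
      eq <- steady_state(params, phi)
      if (!eq$viable) stop("no viable steady state at phi = ", phi)
      n_cells <- max(1L, as.integer(round(eq$cells)))
      lat$c[] <- eq$state[["c"]]
      lat$d[] <- eq$state[["d"]]
      lat$z[] <- eq$state[["z"]]
      for (s in seq_len(L * L))
        lat$cells[[s]] <- data.frame(
          phi = rep(phi, n_cells),
          S = stats::runif(n_cells, 0, params$omega_M),
          strain = rep(1L, n_cells))
      lat
    },
    "two-strain-split" = {
      lat <- make_fixture("steady-monomorphic", params, phi = phi)
      eq2 <- steady_state(params, phi2)
      if (!eq2$viable) stop("no viable steady state at phi2 = ", phi2)
      n2 <- max(1L, as.integer(round(eq2$cells)))
      right <- as.vector(outer(seq_len(L), (ceiling(L / 2) + 1):L,
                               function(r, cc) .site_index(r, cc, L)))
      for (s in right) {
        lat$c[s] <- eq2$state[["c"]]; lat$d[s] <- eq2$state[["d"]]
        lat$z[s] <- eq2$state[["z"]]
        lat$cells[[s]] <- data.frame(
          phi = rep(phi2, n2),
          S = stats::runif(n2, 0, params$omega_M),
          strain = rep(2L, n2))
      }
      lat
    },
    stop("unknown fixture kind: ", kind)
  )
}
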