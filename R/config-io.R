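# Configuration files, artifact writing, and deterministic test fixtures.

#' Default run configuration
#'
#' Nested list of all tunable parameters with the model's reference values:
#' neuron parameters (conductance kind, reversal potentials 0/-80 mV,
#' rest/reset -70 mV, threshold -55 mV, tau_P 20 ms, tau_ref 2 ms,
#' g_E 0.005, g_I 0.11), embedding geometry, the two-component delay model,
#' the stimulus protocol (40 ms period from 200 ms), detection parameters
#' and sweep grids.
#'
#' @return A `run_config` list.
#' @export
default_config <- function() {
  structure(list(
    neuron = list(model_kind = "conductance", V_E = 0, V_I = -80,
                  V_P = -70, V_R = -70, V_Theta = -55, tau_P = 20,
                  tau_ref = 2, g_E = 0.005, g_I = 0.11,
                  a_E = NULL, a_I = NULL),
    embedding = list(C_E = 8000, n_E = 72, gamma = 0.25,
                     gamma_prime = 0.25, N_E = NULL),
    delays = list(tau_A_range = c(0.5, 4.5), tau_B_range = c(0, 0.5)),
    protocol = list(target_pool = 1, period = 40, start = 200,
                    packet_size = NULL, packet_sigma = 0.1, ramp = NULL),
    detection = list(T_w = 3, n_theta_frac = 0.4, min_run = 6,
                     link_window = c(0.5, 6), rate_bin = 20),
    grids = list(n_E = seq(20, 220, by = 4), lambda_E = seq(1, 300, by = 1)),
    sim = list(dt = 0.1, duration = 10000, trials = 100, n_pools = 100),
    seed = 1,
    out_dir = "."), class = "run_config")
}

check_keys <- function(x, ref, path = "") {
  bad <- setdiff(names(x), names(ref))
  if (length(bad))
    stop_invalid("unknown configuration key: %s%s", path, bad[1])
  for (k in names(x)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(x[[k]]))
      check_keys(x[[k]], ref[[k]], paste0(path, k, "."))
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
        is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[k] <- list(override[[k]])  # keeps explicit NULLs
  }
  base
}

#' Load / write a run configuration (YAML)
#'
#' Unspecified keys take the defaults of [default_config()]; unknown keys
#' are rejected with an error naming the offending key path. An empty file
#' yields the full default configuration.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  ref <- default_config()
  check_keys(raw, ref)
  structure(merge_config(unclass(ref), raw), class = "run_config")
}

#' @rdname load_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' @param config A `run_config` (or any serializable list).
#' @return MD5 hex string, embedded in artifact metadata.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

config_neuron_params <- function(config) {
  n <- config$neuron
  if (n$model_kind == "conductance")
    neuron_params("conductance", V_E = n$V_E, V_I = n$V_I, V_P = n$V_P,
                  V_R = n$V_R, V_Theta = n$V_Theta, tau_P = n$tau_P,
                  tau_ref = n$tau_ref, g_E = n$g_E, g_I = n$g_I)
  else
    neuron_params("current", V_E = n$V_E, V_I = n$V_I, V_P = n$V_P,
                  V_R = n$V_R, V_Theta = n$V_Theta, tau_P = n$tau_P,
                  tau_ref = n$tau_ref, a_E = n$a_E, a_I = n$a_I)
}

#' Write a set of result objects to a directory with a manifest
#'
#' Dispatches on class (`rate_table`, `prop_table`, `network_spec`,
#' `spike_data`, `run_config`, plain data frames) and records each written
#' file with its MD5 checksum in `manifest.tsv`.
#'
#' @param objects Named list of objects.
#' @param dir Output directory.
#' @return The manifest data frame (`name`, `file`, `md5`), invisibly.
#' @export
write_artifacts <- function(objects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(objects), function(nm) {
    obj <- objects[[nm]]
    f <- if (inherits(obj, "rate_table")) {
      write_rate_table(obj, file.path(dir, paste0(nm, ".tsv")))
    } else if (inherits(obj, "prop_table")) {
      write_prop_table(obj, file.path(dir, paste0(nm, ".tsv")))
    } else if (inherits(obj, "network_spec")) {
      write_network_spec(obj, file.path(dir, nm))
      file.path(dir, nm, "synapses.tsv")
    } else if (inherits(obj, "spike_data")) {
      write_spikes(obj, file.path(dir, paste0(nm, ".txt")))
    } else if (inherits(obj, "run_config")) {
      write_config(obj, file.path(dir, paste0(nm, ".yaml")))
    } else if (is.data.frame(obj)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      write.table(obj, p, sep = "\t", row.names = FALSE, quote = FALSE)
      p
    } else stop_invalid("no writer for object '%s'", nm)
    data.frame(name = nm, file = f, md5 = unname(tools::md5sum(f)))
  })
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Deterministic synthetic fixtures for tests and demos
#'
#' * `"raster_with_packets"`: a single pool's raster with low-rate Poisson
#'   background and packets of known size planted at known times (ground
#'   truth returned alongside).
#' * `"tiny_embedding"`: a miniature embedding realization.
#' * `"control_chain"`: a short feedforward control chain.
#' Requests above the desk-scale budget (50,000 neurons) are refused.
#'
#' @param kind Fixture kind.
#' @param params Named list overriding the fixture defaults.
#' @param seed Integer seed; same seed gives an identical fixture.
#' @return Fixture object (see details).
#' @export
make_fixture <- function(kind = c("raster_with_packets", "tiny_embedding",
                                  "control_chain"),
                         params = list(), seed = 1) {
  kind <- match.arg(kind)
  if (kind == "raster_with_packets") {
    p <- modifyList(list(n_E = 100, duration = 2000, n_packets = 5,
                         bg_rate_Hz = 2, packet_frac = 0.9,
                         packet_sigma = 0.15), params)
    local_seed(seed, {
      truth <- sort(runif(p$n_packets, 100, p$duration - 100))
      while (any(diff(truth) < 50))
        truth <- sort(runif(p$n_packets, 100, p$duration - 100))
      n_bg <- rpois(1, p$n_E * p$bg_rate_Hz * p$duration / 1000)
      bg <- runif(n_bg, 0, p$duration)
      pk <- unlist(lapply(truth, function(t0)
        rnorm(round(p$packet_frac * p$n_E), t0, p$packet_sigma)))
      list(times = sort(c(bg, pk)), truth = truth, n_E = p$n_E,
           params = p)
    })
  } else if (kind == "tiny_embedding") {
    p <- modifyList(list(C_E = 160, n_E = 16, gamma = 0.25,
                         gamma_prime = 0.25, N_E = NULL), params)
    cfg <- embedding_config(p$C_E, p$n_E, p$gamma, p$gamma_prime,
                            N_E = p$N_E %||% (10 * p$C_E), seed = seed)
    n_tot <- cfg$N_E * (1 + p$gamma)
    if (n_tot > 5e4)
      stop_invalid(paste0("fixture too large (%d neurons > 50000); ",
                          "reduce C_E or N_E"), n_tot)
    build_embedding(cfg)
  } else {
    p <- modifyList(list(n_E = 40, n_pools = 12), params)
    if (p$n_E * p$n_pools > 5e4)
      stop_invalid("fixture too large; reduce n_E or n_pools")
    build_control_chain(p$n_E, p$n_pools, seed = seed)
  }
}
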