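# Run configuration: JSON config parsing with validation and defaults,
# named channel-condition presets, and deterministic test fixtures.

#' Named channel-condition presets
#'
#' The five evaluation conditions used throughout the package's simulations,
#' spanning symmetric and heavily biased channels: `C-0-0` (noise free),
#' `C-5-25` (asymmetric, low error), `C-15-15` (symmetric, low error),
#' `C-25-25` (symmetric, high error) and `C-5-45` (asymmetric, high error —
#' one input nearly non-functional).
#'
#' @param name optional condition name(s); default all.
#' @return A tibble: `condition`, `f0`, `f1`.
#' @examples
#' condition_presets("C-5-45")
#' @export
condition_presets <- function(name = NULL) {
  tbl <- tibble::tribble(
    ~condition, ~f0, ~f1,
    "C-0-0", 0.00, 0.00,
    "C-5-25", 0.05, 0.25,
    "C-15-15", 0.15, 0.15,
    "C-25-25", 0.25, 0.25,
    "C-5-45", 0.05, 0.45
  )
  if (is.null(name)) return(tbl)
  bad <- setdiff(name, tbl$condition)
  if (length(bad)) stop("unknown condition preset: ", paste(bad, collapse = ", "))
  tbl[match(name, tbl$condition), ]
}

config_defaults <- list(
  beta = 0, headroom = 0.02, n = 1000, t_input = NA_real_, seed = NA_integer_
)

#' Load and validate a run configuration
#'
#' Reads a JSON configuration describing a decoder/channel/simulation run.
#' Recognised keys: `name`, `condition` (a preset name, expanded to
#' `f0`/`f1`), `k`, `beta`, `f0`, `f1`, `f0_dec`, `f1_dec`, `headroom`,
#' `model` (`"bernoulli"` or `"gilbert_elliott"`), `t` (burstiness), `n`,
#' `t_input`, `seed`, `out`. Unknown keys are rejected with a message naming
#' the key; range violations name the offending key. Defaults: `beta = 0`,
#' `headroom = 0.02`, configured rates = true rates + headroom.
#'
#' @param path path to a JSON file, or a JSON string, or a list.
#' @return A validated named list of class `run_config`.
#' @export
load_config <- function(path) {
  raw <- if (is.list(path)) {
    path
  } else if (is.character(path) && length(path) == 1 && file.exists(path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (is.character(path) && grepl("^\\s*\\{", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config file not found: ", path)
  }
  allowed <- c("name", "condition", "k", "beta", "f0", "f1", "f0_dec",
               "f1_dec", "headroom", "model", "t", "n", "t_input", "seed",
               "out")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(config_defaults, raw)
  if (!is.null(cfg$condition)) {
    preset <- condition_presets(cfg$condition)
    cfg$f0 <- preset$f0
    cfg$f1 <- preset$f1
  }
  if (is.null(cfg$k)) stop("config key `k` is required")
  if (cfg$k < 1 || cfg$k != floor(cfg$k)) stop("config key `k` must be a positive integer")
  if (is.null(cfg$f0)) stop("config key `f0` is required")
  if (is.null(cfg$f1)) cfg$f1 <- cfg$f0
  for (key in c("f0", "f1")) {
    v <- cfg[[key]]
    if (v < 0 || v > 0.5) stop("config key `", key, "` must lie in [0, 0.5]")
  }
  if (cfg$beta < 0) stop("config key `beta` must be >= 0")
  if (is.null(cfg$f0_dec)) cfg$f0_dec <- cfg$f0 + cfg$headroom
  if (is.null(cfg$f1_dec)) cfg$f1_dec <- cfg$f1 + cfg$headroom
  for (key in c("f0_dec", "f1_dec")) {
    v <- cfg[[key]]
    if (v < 0 || v >= 0.5) stop("config key `", key, "` must lie in [0, 0.5)")
  }
  if (is.null(cfg$model)) cfg$model <- "bernoulli"
  if (!cfg$model %in% c("bernoulli", "gilbert_elliott")) {
    stop("config key `model` must be \"bernoulli\" or \"gilbert_elliott\"")
  }
  if (cfg$model == "gilbert_elliott") {
    if (is.null(cfg[["t"]]) || cfg[["t"]] <= 1) stop("config key `t` must be > 1")
  }
  structure(cfg, class = "run_config")
}

#' Build the decoder config and channel described by a run configuration
#'
#' @param cfg a `run_config` from [load_config()].
#' @return A list with `config` (a [decoder_config()]) and `channel`.
#' @export
realise_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  channel <- if (cfg$model == "gilbert_elliott") {
    gilbert_elliott_channel((cfg$f0 + cfg$f1) / 2, cfg[["t"]])
  } else {
    binary_channel(cfg$f0, cfg$f1)
  }
  list(
    config = decoder_config(k = cfg$k, beta = cfg$beta,
                            f0 = cfg$f0_dec, f1 = cfg$f1_dec),
    channel = channel
  )
}

#' Serialise a decoder to JSON
#'
#' Captures breakpoints, cumulative values, input count and configuration so
#' a session can be resumed or frozen as a test fixture.
#'
#' @param dec a `horstein_decoder`.
#' @return A JSON string.
#' @export
decoder_to_json <- function(dec) {
  stopifnot(inherits(dec, "horstein_decoder"))
  jsonlite::toJSON(list(
    x = dec$cdf$x, Fx = dec$cdf$Fx, n_inputs = dec$n_inputs,
    k = dec$config$k, beta = dec$config$beta,
    f0 = dec$config$f0, f1 = dec$config$f1,
    prior = dec$config$prior
  ), auto_unbox = TRUE, digits = NA)
}

#' Restore a decoder from JSON
#'
#' @param json output of [decoder_to_json()].
#' @return A `horstein_decoder` (without history).
#' @export
decoder_from_json <- function(json) {
  s <- jsonlite::fromJSON(json)
  prior <- if (length(s$prior)) as.numeric(s$prior) else NULL
  cfg <- decoder_config(k = s$k, beta = s$beta, f0 = s$f0, f1 = s$f1,
                        prior = prior)
  dec <- init_decoder(cfg, store_history = FALSE)
  dec$cdf <- list(x = s$x, Fx = s$Fx)
  dec$entropy <- pw_entropy(dec$cdf)
  dec$n_inputs <- as.integer(s$n_inputs)
  dec
}

#' Deterministic fixture bundle for tests and demos
#'
#' Produces a reproducible bundle: hand-checkable 1-3 step decoder states
#' with their expected posterior masses, random bit sequences, and the
#' channel-condition presets. Regeneration with the same seed is identical.
#'
#' @param seed integer seed.
#' @return A named list with elements `seed`, `conditions`,
#'   `single_update` (the f' = 0.1, b = 0 one-step state, left mass 0.9),
#'   `three_step` (a 3-update state with its step-by-step left masses),
#'   `bits` (a random 64-bit sequence), `decoder_json`.
#' @export
make_fixtures <- function(seed = 0) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cfg <- decoder_config(k = 4, beta = 0, f0 = 0.1)
  one <- decoder_update(init_decoder(cfg), 0)
  three <- init_decoder(cfg)
  bits3 <- c(0L, 1L, 0L)
  for (b in bits3) three <- decoder_update(three, b)
  # left-of-split posterior mass after each update, from the Bayes factors
  p <- bayes_p(0.1, 0.1)
  masses <- c(p, 1 - bayes_q(0.1, 0.1), p)
  list(
    seed = seed,
    conditions = condition_presets(),
    single_update = list(decoder = one, left_mass = p),
    three_step = list(decoder = three, bits = bits3, split_masses = masses),
    bits = sample(0:1, 64, replace = TRUE),
    decoder_json = decoder_to_json(one)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
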