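#' Read an experiment configuration file (YAML or JSON)
#'
#' Light-weight configuration loader for scripted runs: a YAML (requires
#' the `yaml` package) or JSON file describing an experiment, validated
#' against a minimal schema. Recognized top-level fields: `seed`
#' (integer, required when any `noise` sigma is non-zero), `noise` (named
#' sigmas passed to [experiment_truth()]), `protocol` (arguments of
#' [simulate_experiment()]), `phantom` (arguments of [phantom_spec()]),
#' `output_dir`. Unknown fields are rejected to catch typos.
#'
#' @param path File path (`.yaml`, `.yml` or `.json`).
#' @return A named list with class `experiment_config` and attribute
#'   `config_hash` (hex digest of the normalized content, for traceable
#'   logs).
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lower <- tolower(path)
  cfg <- if (grepl("\\.(yaml|yml)$", lower)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", lower)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format (need .yaml/.yml/.json): ", path)
  }
  if (!is.list(cfg)) stop("config must be a mapping/object: ", path)
  allowed <- c("seed", "noise", "protocol", "phantom", "output_dir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  sig <- unlist(cfg$noise)
  if (is.null(cfg$seed) && !is.null(sig) && any(sig > 0)) {
    stop("config enables stochastic steps (non-zero noise) but has no seed")
  }
  attr(cfg, "config_hash") <- .config_hash(cfg)
  class(cfg) <- c("experiment_config", "list")
  cfg
}

# Small FNV-1a style hash of the serialized config (hex string); avoids a
# digest dependency while still giving traceable run identifiers.
.config_hash <- function(cfg) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                                 digits = NA)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
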