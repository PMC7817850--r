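#' Serialize a generative model to JSON
#'
#' Writes the documented model-spec format: top-level keys `n_states`,
#' `n_outcomes`, `n_actions`, `horizon`, `A` (nested lists, row-major,
#' `[outcome][state]`), `B` (list over actions of `[next][prev]`), `D`,
#' `C` (object with key `log_probs`, a list over time steps of vectors over
#' outcomes), optional `E` (`[outcome][policy]`) and `E_counts`, `policies`
#' (list of 1-based action-index lists) and `gamma`. A JSON-schema document
#' describing the format ships at
#' `system.file("extdata", "model-schema.json", package = "actinf")`.
#'
#' @param model A valid `"generative_model"`.
#' @param path Optional file path; when `NULL` the JSON text is returned.
#' @return The JSON text (invisibly when written to `path`).
#' @seealso [load_model()]
#' @export
save_model <- function(model, path = NULL) {
  assert_valid_model(model)
  spec <- list(
    n_states = model$n_states,
    n_outcomes = model$n_outcomes,
    n_actions = model$n_actions,
    horizon = model$horizon,
    A = matrix_to_rows(model$A),
    B = lapply(model$B, matrix_to_rows),
    D = I(model$D),
    C = list(log_probs = lapply(seq_len(ncol(model$lnC)),
                                function(tau) I(model$lnC[, tau]))),
    policies = lapply(seq_len(nrow(model$policies)),
                      function(i) I(model$policies[i, ])),
    gamma = model$gamma
  )
  if (!is.null(model$E)) spec$E <- matrix_to_rows(model$E)
  if (!is.null(model$E_counts)) spec$E_counts <- matrix_to_rows(model$E_counts)
  txt <- jsonlite::toJSON(spec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

# I() keeps length-1 rows serialized as arrays under auto_unbox
matrix_to_rows <- function(m) lapply(seq_len(nrow(m)), function(i) I(m[i, ]))

#' Load a generative model from a JSON (or YAML) spec
#'
#' Parses the format written by [save_model()]. Round-tripping is lossless
#' up to float representation. Missing required keys raise a parse error
#' naming the offending path (e.g. `/D`); a structurally parseable spec
#' whose contents violate a model invariant raises a validation error.
#' YAML is accepted as a convenience dialect when the `yaml` package is
#' installed.
#'
#' @param text A file path, or a character string holding the spec itself.
#' @param format `"auto"` (default: by file extension / first character),
#'   `"json"` or `"yaml"`.
#' @return A valid `"generative_model"`.
#' @export
load_model <- function(text, format = c("auto", "json", "yaml")) {
  format <- match.arg(format)
  is_file <- length(text) == 1L && !grepl("[{\n:]", text) && file.exists(text)
  raw <- if (is_file) paste(readLines(text, warn = FALSE), collapse = "\n") else text
  if (format == "auto") {
    format <- if (is_file && grepl("\\.ya?ml$", text, ignore.case = TRUE)) "yaml"
              else if (grepl("^\\s*\\{", raw)) "json"
              else if (is_file) "json"
              else if (requireNamespace("yaml", quietly = TRUE)) "yaml"
              else "json"
  }
  spec <- if (format == "yaml") {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML specs require the 'yaml' package", call. = FALSE)
    }
    yaml::yaml.load(raw)
  } else {
    jsonlite::fromJSON(raw, simplifyVector = FALSE)
  }
  spec_to_model(spec)
}

spec_to_model <- function(spec) {
  need <- function(key) {
    if (is.null(spec[[key]])) {
      stop(sprintf("model spec parse error: missing required key at path /%s",
                   key), call. = FALSE)
    }
    spec[[key]]
  }
  n_states <- as.integer(need("n_states"))
  n_outcomes <- as.integer(need("n_outcomes"))
  n_actions <- as.integer(need("n_actions"))
  horizon <- as.integer(need("horizon"))

  A <- rows_to_matrix(need("A"), n_outcomes, n_states, "/A")
  Braw <- need("B")
  if (length(Braw) != n_actions) {
    stop("model spec parse error: /B must list one matrix per action",
         call. = FALSE)
  }
  B <- lapply(seq_along(Braw), function(a) {
    rows_to_matrix(Braw[[a]], n_states, n_states, sprintf("/B/%d", a))
  })
  D <- as.numeric(unlist(need("D")))

  Craw <- need("C")
  if (!is.null(Craw$log_probs)) {
    C <- do.call(cbind, lapply(Craw$log_probs, function(v) as.numeric(unlist(v))))
    pref_kind <- "log_probs"
  } else if (!is.null(Craw$utilities)) {
    C <- do.call(cbind, lapply(Craw$utilities, function(v) as.numeric(unlist(v))))
    pref_kind <- "utilities"
  } else {
    stop("model spec parse error: /C must contain 'log_probs' or 'utilities'",
         call. = FALSE)
  }

  pol <- need("policies")
  policies <- do.call(rbind, lapply(pol, function(p) as.integer(unlist(p))))

  E <- if (!is.null(spec$E)) {
    rows_to_matrix(spec$E, n_outcomes, nrow(policies), "/E")
  } else NULL
  E_counts <- if (!is.null(spec$E_counts)) {
    rows_to_matrix(spec$E_counts, n_outcomes, nrow(policies), "/E_counts")
  } else NULL

  model <- generative_model(
    A = A, B = B, D = D, C = C, horizon = horizon, policies = policies,
    gamma = if (is.null(spec$gamma)) 1 else as.numeric(spec$gamma),
    E = E, E_counts = E_counts, preferences = pref_kind)

  rep <- validate_model(model)
  if (nrow(rep) > 0L) {
    stop("model spec validation error: ",
         paste(unique(rep$code), collapse = ", "), call. = FALSE)
  }
  model
}

rows_to_matrix <- function(rows, nr, nc, path) {
  m <- try(do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r)))),
           silent = TRUE)
  if (inherits(m, "try-error") || is.null(m) ||
      nrow(m) != nr || ncol(m) != nc) {
    stop(sprintf("model spec parse error: %s is not a %d x %d matrix",
                 path, nr, nc), call. = FALSE)
  }
  m
}
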