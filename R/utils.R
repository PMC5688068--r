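# Shared helpers for the wide "cohort table" layout: metadata columns
# (subject_id, group, replicate) followed by one numeric column per feature.

.meta_cols <- c("subject_id", "group", "replicate")

.feature_cols <- function(data) {
  setdiff(names(data), .meta_cols)
}

# Extract the numeric feature block as a matrix with subject ids as rownames.
.feature_matrix <- function(data) {
  feats <- .feature_cols(data)
  X <- as.matrix(data[feats])
  if (!is.numeric(X)) {
    abort("Feature columns must all be numeric.", class = "voclearn_error_input")
  }
  if ("subject_id" %in% names(data)) rownames(X) <- as.character(data$subject_id)
  X
}

.check_two_groups <- function(group) {
  lv <- unique(as.character(group[!is.na(group)]))
  if (length(lv) != 2) {
    abort(
      sprintf("`group` must have exactly two levels, found %d.", length(lv)),
      class = "voclearn_error_input"
    )
  }
  invisible(lv)
}

# Positive class: explicit choice, else the second factor level (convention:
# levels are c(control, case), e.g. c("NW", "OW/Ob")).
.positive_class <- function(group, positive = NULL) {
  lv <- if (is.factor(group)) levels(group) else sort(unique(as.character(group)))
  if (is.null(positive)) {
    return(lv[length(lv)])
  }
  if (!positive %in% lv) {
    abort(sprintf("`positive` class '%s' not found in group labels.", positive),
          class = "voclearn_error_parameter")
  }
  positive
}

# y coded -1 (control) / +1 (positive class)
.encode_y <- function(group, positive) {
  ifelse(as.character(group) == positive, 1, -1)
}

.check_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "voclearn_error_parameter")
  }
  as.integer(x)
}

.check_prob <- function(x, name, open_left = TRUE, open_right = FALSE) {
  lo_ok <- if (open_left) all(x > 0) else all(x >= 0)
  hi_ok <- if (open_right) all(x < 1) else all(x <= 1)
  if (length(x) < 1 || anyNA(x) || !lo_ok || !hi_ok) {
    abort(sprintf("`%s` must lie in %s0, 1%s.", name,
                  if (open_left) "(" else "[", if (open_right) ")" else "]"),
          class = "voclearn_error_parameter")
  }
  x
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
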