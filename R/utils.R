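# shared internal helpers: argument checks, seeding, hashing, logging

abort_arg <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) abort_arg(...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a child seed from a master seed and a salt
#'
#' All randomness in a run flows from one integer seed; subsystems draw
#' their own streams through deterministic child seeds so that, e.g.,
#' simulating one extra case does not perturb the others. Kept within
#' the 32-bit signed integer range.
#' @keywords internal
derive_seed <- function(seed, salt) {
  stopifnot(is_count(seed))
  salt_num <- if (is.character(salt)) {
    sum(as.integer(charToRaw(salt)) * seq_along(charToRaw(salt)))
  } else {
    as.numeric(salt)
  }
  as.integer((abs(seed) * 69069 + salt_num * 7919 + 12345) %% 2147483647)
}

# evaluate expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# md5 of an R object via canonical serialization (version 3, no header refs)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 3, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Largest-remainder integer allocation of n items to fractions
#' @keywords internal
allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

log_msg <- function(level, fmt, ...) {
  msg <- sprintf("[%s] %s %s", level,
                 format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  logfile <- getOption("svwave.logfile", NULL)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
  invisible(msg)
}
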