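# internal helpers shared across modules

.facefem_env <- new.env(parent = emptyenv())
.facefem_env$solve_count <- 0L

#' Number of finite-element solves performed in this session
#'
#' Incremented by every call to [solve_viscoelastic()] and [solve_elastic()].
#' Used to verify cache contracts (a cached pipeline rerun performs zero new
#' solves).
#'
#' @param reset if `TRUE`, reset the counter to zero after reading it.
#' @return integer count of solves since load (or last reset).
#' @export
fem_solve_count <- function(reset = FALSE) {
  n <- .facefem_env$solve_count
  if (reset) .facefem_env$solve_count <- 0L
  n
}

.bump_solve_count <- function() {
  .facefem_env$solve_count <- .facefem_env$solve_count + 1L
  invisible(NULL)
}

# evaluate code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stable content hash for cache keys
hash_object <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
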