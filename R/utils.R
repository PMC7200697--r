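#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join anti_join semi_join bind_rows n count distinct across rename
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_chr map_int pmap pmap_chr walk imap
#' @importFrom stats median rpois runif rnorm rlnorm setNames quantile sd pt
#' @importFrom utils head tail
NULL

# Named RNG substreams derived from one user-facing seed, so each generator
# (population, images, variants, backcross) is independently reproducible.
.substreams <- c(population = 11L, images = 23L, variants = 37L,
                 backcross = 53L, pipeline = 71L)

derive_seed <- function(seed, stream) {
  if (!stream %in% names(.substreams)) {
    abort(paste0("unknown RNG substream: ", stream))
  }
  seed <- as.integer(seed)
  (seed %% 1000000L) * 1009L + .substreams[[stream]]
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

check_prob_vector <- function(p, what, tol = 1e-9) {
  if (any(is.na(p)) || any(p < 0) || abs(sum(p) - 1) > tol) {
    abort(paste0("invalid probability vector `", what,
                 "`: entries must be >= 0 and sum to 1 (got sum = ",
                 format(sum(p), digits = 12), ")"))
  }
  invisible(p)
}

round1 <- function(x) round(x, 1)
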