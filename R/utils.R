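# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

STAGES <- c("normal", "LGA", "HGA", "cancer")
PROMOTER_CATEGORIES <- c("TSS200", "TSS1500", "5'UTR", "1stExon")
REGION_CATEGORIES <- c(PROMOTER_CATEGORIES, "Body", "3'UTR", "intergenic")
ISLAND_RELATIONS <- c("island", "shore", "shelf", "open_sea")
SEX_CHROMS <- c("chrX", "chrY")

assert_beta_matrix <- function(betas, arg = "betas") {
  if (!is.matrix(betas) || !is.numeric(betas)) {
    stop(sprintf("`%s` must be a numeric matrix (probes x samples)", arg), call. = FALSE)
  }
  if (is.null(rownames(betas)) || is.null(colnames(betas))) {
    stop(sprintf("`%s` must have probe rownames and sample colnames", arg), call. = FALSE)
  }
  vals <- betas[is.finite(betas)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1)) {
    stop(sprintf("`%s` has values outside [0, 1]", arg), call. = FALSE)
  }
  invisible(betas)
}

assert_manifest <- function(manifest, arg = "manifest") {
  required <- c("probe_id", "chrom", "pos", "gene", "region_category",
                "island_relation", "snp_flagged")
  if (!is.data.frame(manifest) || !all(required %in% names(manifest))) {
    stop(sprintf("`%s` must be a data.frame with columns: %s",
                 arg, paste(required, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(manifest$probe_id)) {
    stop(sprintf("`%s` has duplicated probe_id values", arg), call. = FALSE)
  }
  invisible(manifest)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)  # x first: keeps dim attributes

`%||%` <- function(a, b) if (is.null(a)) b else a
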