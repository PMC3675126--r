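#' Simulation parameters for the coalescent haplotype pool
#'
#' The pool emulates a neutral, constant-size coalescent population of
#' haploid genomes made of two independently assorting chromosomes. The
#' first chromosome ("causal") will carry the causal sites chosen later;
#' the second ("null") never does, so false positives can be accounted
#' separately for linked and unlinked variants.
#'
#' @param n_haplotypes Number of haploid genomes in the pool (even, >= 4).
#' @param chrom_lengths Lengths in bp of the causal and null chromosomes.
#' @param mu Mutation rate per bp per generation.
#' @param rho Recombination rate per bp per generation.
#' @param effective_size Diploid effective population size Ne. Defaults to
#'   `n_haplotypes / 2` so that the sampled haplotypes are the whole
#'   population.
#' @param seed Integer seed for the coalescent simulator.
#'
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_haplotypes = 15000L,
                       chrom_lengths = c(500000L, 500000L),
                       mu = 1e-8,
                       rho = 1e-8,
                       effective_size = n_haplotypes / 2,
                       seed = 1L) {
  n_haplotypes <- as.integer(n_haplotypes)
  if (is.na(n_haplotypes) || n_haplotypes < 4L || n_haplotypes %% 2L != 0L)
    stop("`n_haplotypes` must be an even integer >= 4", call. = FALSE)
  if (length(chrom_lengths) != 2L || any(chrom_lengths <= 0))
    stop("`chrom_lengths` must be two positive lengths", call. = FALSE)
  if (mu < 0 || rho < 0) stop("`mu` and `rho` must be >= 0", call. = FALSE)
  if (effective_size <= 0) stop("`effective_size` must be > 0", call. = FALSE)
  structure(
    list(n_haplotypes = n_haplotypes,
         chrom_lengths = as.numeric(chrom_lengths),
         mu = mu, rho = rho,
         effective_size = effective_size,
         seed = as.integer(seed)),
    class = "sim_params")
}

poolsim_script <- function() {
  path <- system.file("python", "poolsim.py", package = "bvlr")
  if (!nzchar(path)) stop("poolsim.py not found in installed package", call. = FALSE)
  path
}

#' Generate coalescent haplotype pool files
#'
#' Low-level batch interface: runs the msprime-backed simulator once and
#' writes `n` pools to `dir` (one pair of `.sites`/`.bin` files per
#' chromosome per pool). Use [read_pool()] to load a pool, or
#' [simulate_pool()] for the single-pool convenience wrapper.
#'
#' @param params A [sim_params()] object.
#' @param n Number of replicate pools to generate.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
simulate_pool_files <- function(params, n = 1L, dir = tempfile("pools")) {
  stopifnot(inherits(params, "sim_params"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  if (!nzchar(python))
    stop("No `python` interpreter with msprime found on PATH", call. = FALSE)
  args <- c(poolsim_script(), dir, n, params$n_haplotypes,
            params$effective_size, params$chrom_lengths[1],
            params$chrom_lengths[2], params$mu, params$rho, params$seed)
  out <- suppressWarnings(system2(python, shQuote(as.character(args)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if ((!is.null(status) && status != 0) || !any(grepl("^OK$", out)))
    stop("coalescent simulation failed:\n", paste(out, collapse = "\n"),
         call. = FALSE)
  invisible(dir)
}

read_pool_chrom <- function(dir, i, chrom, n_hap) {
  sites_path <- file.path(dir, sprintf("pool%d_%s.sites", i, chrom))
  bin_path <- file.path(dir, sprintf("pool%d_%s.bin", i, chrom))
  info <- file.info(sites_path)
  if (is.na(info$size)) stop("pool files not found in ", dir, call. = FALSE)
  if (info$size == 0)
    return(list(H = matrix(0L, n_hap, 0L),
                sites = data.frame(chrom = character(0), pos = integer(0),
                                   maf = numeric(0))))
  tab <- utils::read.table(sites_path, col.names = c("pos", "maf"))
  ns <- nrow(tab)
  con <- file(bin_path, "rb")
  on.exit(close(con))
  vals <- as.integer(readBin(con, what = "raw", n = ns * n_hap))
  if (length(vals) != ns * n_hap)
    stop("truncated pool genotype file: ", bin_path, call. = FALSE)
  list(H = matrix(vals, nrow = n_hap),
       sites = data.frame(chrom = chrom, pos = as.integer(tab$pos),
                          maf = tab$maf))
}

#' Read one generated pool from disk
#'
#' @param dir Directory written by [simulate_pool_files()].
#' @param i Pool index within the batch (1-based).
#' @param params The [sim_params()] used to generate the batch.
#' @return A `haplotype_pool`: list with `haplotypes` (n_haplotypes x sites
#'   0/1 integer matrix, 1 = pool minor allele), `sites` (data.frame with
#'   `chrom` in `{"causal","null"}`, 1-based `pos`, pool `maf`), and
#'   `params`.
#' @export
read_pool <- function(dir, i = 1L, params) {
  n_hap <- params$n_haplotypes
  cc <- read_pool_chrom(dir, i, "causal", n_hap)
  nn <- read_pool_chrom(dir, i, "null", n_hap)
  pool <- list(haplotypes = cbind(cc$H, nn$H),
               sites = rbind(cc$sites, nn$sites),
               params = params)
  rownames(pool$sites) <- NULL
  if (ncol(pool$haplotypes) > 0)
    colnames(pool$haplotypes) <- variant_ids(pool$sites)
  class(pool) <- "haplotype_pool"
  pool
}

variant_ids <- function(sites) paste0(sites$chrom, "_", sites$pos)

#' Simulate a coalescent haplotype pool
#'
#' Generates `n_haplotypes` haploid genomes over two independently
#' assorting chromosomes under the standard neutral coalescent with
#' recombination (constant population size `effective_size`, infinite-sites
#' style biallelic mutations). Each polymorphic site is stored with 1 coding
#' the pool minor allele (columns with derived frequency > 0.5 are folded),
#' so pool MAF is always in (0, 0.5].
#'
#' @param params A [sim_params()] object.
#' @return A `haplotype_pool` object; see [read_pool()].
#' @examples
#' \dontrun{
#' pool <- simulate_pool(sim_params(n_haplotypes = 200, seed = 1))
#' }
#' @export
simulate_pool <- function(params = sim_params()) {
  dir <- simulate_pool_files(params, n = 1L)
  on.exit(unlink(dir, recursive = TRUE))
  read_pool(dir, 1L, params)
}

#' @export
print.haplotype_pool <- function(x, ...) {
  ns <- table(factor(x$sites$chrom, levels = c("causal", "null")))
  cat("Haplotype pool:", nrow(x$haplotypes), "haplotypes;",
      ns[["causal"]], "sites on causal chromosome,",
      ns[["null"]], "on null chromosome\n")
  invisible(x)
}

central_region <- function(length_bp, half_width = 50000) {
  mid <- length_bp / 2
  c(lower = mid - half_width + 1, upper = mid + half_width)
}

#' Choose causal sites from the pool
#'
#' Draws `k` distinct sites uniformly at random among sites on the causal
#' chromosome that lie in its central 100 kb and whose pool MAF falls in
#' `maf_interval` (half-open, `[low, high)`). The risk allele is always the
#' minor allele.
#'
#' @param pool A `haplotype_pool`.
#' @param maf_interval Numeric `c(low, high)` MAF bounds as fractions.
#' @param k Number of causal sites (default 3).
#' @return A `causal_spec`: list with `site_indices` (column indices into
#'   the pool), `maf_interval` and `k`.
#' @export
select_causal_sites <- function(pool, maf_interval, k = 3L) {
  stopifnot(inherits(pool, "haplotype_pool"), length(maf_interval) == 2L)
  reg <- central_region(pool$params$chrom_lengths[1])
  ok <- pool$sites$chrom == "causal" &
    pool$sites$pos >= reg[["lower"]] & pool$sites$pos <= reg[["upper"]] &
    pool$sites$maf >= maf_interval[1] & pool$sites$maf < maf_interval[2]
  idx <- which(ok)
  if (length(idx) < k) {
    stop(structure(
      class = c("bvlr_retry_error", "error", "condition"),
      list(message = sprintf(
             "only %d site(s) qualify for MAF interval [%g, %g); need %d -- regenerate the pool",
             length(idx), maf_interval[1], maf_interval[2], k),
           call = NULL)))
  }
  picked <- if (length(idx) == 1L) idx else sample(idx, k)
  structure(list(site_indices = sort(picked),
                 maf_interval = as.numeric(maf_interval), k = as.integer(k)),
            class = "causal_spec")
}

#' Write / read a pool as ms-style haplotype text
#'
#' The format has one header line per chromosome (`//`, then `segsites:`,
#' then `positions:` in bp), followed by one 0/1 string per haplotype.
#'
#' @param pool A `haplotype_pool`.
#' @param path Output file.
#' @return `path` invisibly (writer); a `haplotype_pool` (reader — note the
#'   reader recomputes pool MAF from the haplotypes).
#' @export
write_pool_ms <- function(pool, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("bvlr-pool n_haplotypes=%d lengths=%s",
                     nrow(pool$haplotypes),
                     paste(pool$params$chrom_lengths, collapse = ",")), con)
  for (ch in c("causal", "null")) {
    sel <- pool$sites$chrom == ch
    writeLines(c("//", paste("segsites:", sum(sel)),
                 paste("positions:", paste(pool$sites$pos[sel], collapse = " "))),
               con)
    if (any(sel)) {
      H <- pool$haplotypes[, sel, drop = FALSE]
      writeLines(apply(H, 1, paste, collapse = ""), con)
    } else {
      writeLines(rep("", nrow(pool$haplotypes)), con)
    }
  }
  invisible(path)
}

#' @rdname write_pool_ms
#' @export
read_pool_ms <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^bvlr-pool ", "", lines[1]), " ")[[1]]
  n_hap <- as.integer(sub("n_haplotypes=", "", hdr[1]))
  lens <- as.numeric(strsplit(sub("lengths=", "", hdr[2]), ",")[[1]])
  blocks <- which(lines == "//")
  stopifnot(length(blocks) == 2L)
  parse_block <- function(start, chrom) {
    pos_line <- sub("^positions: ?", "", lines[start + 2])
    pos <- if (nzchar(pos_line)) as.integer(strsplit(pos_line, " ")[[1]]) else integer(0)
    rows <- lines[(start + 3):(start + 2 + n_hap)]
    H <- if (length(pos)) {
      do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
    } else matrix(0L, n_hap, 0L)
    f <- colMeans(H)
    list(H = H, sites = data.frame(chrom = chrom, pos = pos,
                                   maf = pmin(f, 1 - f)))
  }
  cc <- parse_block(blocks[1], "causal")
  nn <- parse_block(blocks[2], "null")
  params <- sim_params(n_haplotypes = n_hap, chrom_lengths = lens)
  pool <- list(haplotypes = cbind(cc$H, nn$H),
               sites = rbind(cc$sites, nn$sites), params = params)
  rownames(pool$sites) <- NULL
  if (ncol(pool$haplotypes) > 0)
    colnames(pool$haplotypes) <- variant_ids(pool$sites)
  class(pool) <- "haplotype_pool"
  pool
}

#' Watterson's expected number of segregating sites
#'
#' Closed-form neutral expectation `theta * sum_{i=1}^{n-1} 1/i` with
#' `theta = 4 * Ne * mu * L`, used as an oracle for the pool simulator.
#'
#' @param n_haplotypes Sample size (number of haplotypes).
#' @param ne Diploid effective population size.
#' @param mu Mutation rate per bp per generation.
#' @param length_bp Sequence length in bp.
#' @return Expected segregating-site count.
#' @export
watterson_expected_s <- function(n_haplotypes, ne, mu, length_bp) {
  4 * ne * mu * length_bp * sum(1 / seq_len(n_haplotypes - 1))
}
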