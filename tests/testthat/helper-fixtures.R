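# Shared fixture builders and independent oracles for the test suite.

# long-format viability table for hand-constructed curves:
# `curves` is a named list organoid -> list(drug -> ic50) built from a 4PL
# with the given parameters, exact (no noise) unless noise_sd > 0.
make_viability <- function(curves, doses = dose_grid(), n_replicates = 3,
                           top = 1, bottom = 0.1, hill = 1, noise_sd = 0,
                           vehicle_signal = 1) {
  rows <- list()
  for (org in names(curves)) {
    for (drug in names(curves[[org]])) {
      ic <- curves[[org]][[drug]]
      for (conc in c(doses, 0)) {
        v <- if (conc == 0) vehicle_signal else fourpl(conc, top, bottom, hill, ic)
        for (r in seq_len(n_replicates)) {
          eps <- if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
          rows[[length(rows) + 1]] <- data.frame(
            organoid = org, drug = drug, concentration_um = conc,
            replicate = r, signal = max(0, v + eps),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

# minimal VCF writer; records: data.frame with chrom, pos, ref, alt, info
write_test_vcf <- function(records, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Variant class\">",
           "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(records) > 0) {
    info <- if ("info" %in% names(records)) records$info else "."
    paste(records$chrom, records$pos, ".", records$ref, records$alt,
          ".", "PASS", info, sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  path
}

# independent Mann-Whitney oracle: U and exact two-sided p by enumerating
# every assignment of the pooled VALUES to group A (not via ranks)
mw_oracle <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  U_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  U_obs <- U_of(a, b)
  sets <- utils::combn(length(pool), na)
  U_all <- apply(sets, 2, function(ix) U_of(pool[ix], pool[-ix]))
  p <- min(1, 2 * min(mean(U_all <= U_obs + 1e-9), mean(U_all >= U_obs - 1e-9)))
  list(U = U_obs, p.value = p)
}

# trapezoid oracle: fine-grid Riemann sum of the piecewise-linear
# interpolant of (log10 dose, viability)
auc_riemann_oracle <- function(dose_um, viability, n_grid = 200001) {
  l <- log10(sort(dose_um))
  v <- pmax(viability[order(dose_um)], 0)
  g <- seq(min(l), max(l), length.out = n_grid)
  f <- stats::approx(l, v, xout = g)$y
  mean((f[-1] + f[-n_grid]) / 2) * (max(l) - min(l))
}
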