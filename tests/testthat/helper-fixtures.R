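# shared fixtures and independent oracles

# brute-force minor-allele frequency: tally individual allele characters,
# independent of compute_maf's implementation
brute_force_maf <- function(raw) {
  vapply(seq_along(raw$marker_ids), function(j) {
    chars <- unlist(strsplit(raw$calls[, j], ""))
    tab <- table(chars)
    if (length(tab) == 1L) return(0)
    min(tab) / length(chars)
  }, numeric(1))
}

# brute-force continuous metrics from first principles
brute_force_continuous <- function(y, y_hat) {
  list(
    mse = sum((y - y_hat)^2) / length(y),
    rmse = sqrt(sum((y - y_hat)^2) / length(y)),
    mae = sum(abs(y - y_hat)) / length(y),
    r2 = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2),
    pearson_r = sum((y - mean(y)) * (y_hat - mean(y_hat))) /
      sqrt(sum((y - mean(y))^2) * sum((y_hat - mean(y_hat))^2))
  )
}

# brute-force binary MCC from raw confusion counts
brute_force_mcc_binary <- function(tp, tn, fp, fn) {
  (tp * tn - fp * fn) / sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
}

# small genotype CSV on disk
write_fixture_csv <- function(raw, path = tempfile(fileext = ".csv")) {
  write_genotype_csv(raw, path)
  path
}

# dense ridge solve used as the RR-BLUP oracle
ridge_oracle <- function(Z, y, lambda) {
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  solve(crossprod(Zc) + lambda * diag(ncol(Z)), crossprod(Zc, yc))[, 1L]
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

# run the CLI script in a subprocess that sees the same library paths
run_cli <- function(args) {
  script <- system.file("cli", "gselect.R", package = "gselect")
  system2(rscript_bin(), c(script, args), stdout = TRUE, stderr = TRUE,
          env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
}
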