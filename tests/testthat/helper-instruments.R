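# random harmonized-instrument sets and small panel builders used across tests

rand_instruments <- function(K, seed) {
  set.seed(seed)
  data.frame(
    rsid = sprintf("rs%03d", seq_len(K)),
    X = stats::runif(K, 0.01, 0.1) * sample(c(-1, 1), K, replace = TRUE),
    se_X = 0,
    Y = stats::rnorm(K, 0, 0.05),
    se_Y = stats::runif(K, 0.005, 0.05),
    dataset = "sim",
    stringsAsFactors = FALSE
  )
}

make_panel <- function(df, trait = "FG", dataset = "d") {
  defaults <- list(chrom = 1L, pos = 1L, ref = "T", alt = "C",
                   eaf = 0.3, se = 0.01, pval = 1e-10)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- rep(defaults[[nm]], length.out = nrow(df))
  if (!is.null(df$pos) && nrow(df) > 0 && all(df$pos == 1L)) df$pos <- seq_len(nrow(df))
  assoc_panel(df, trait = trait, dataset = dataset)
}

write_tsv_tmp <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}
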