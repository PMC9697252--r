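# Shared easy-phantom benchmark (604 objects: 151 scans x 4 objects,
# balanced) and the three seeded hierarchy training runs on its 70/30
# split. Built lazily once per test session and reused by every file
# that needs trained models. Training uses a reduced epoch budget (8
# epochs, patience 3): the easy benchmark converges within a few epochs.

.bench <- new.env(parent = emptyenv())

benchConfig <- function() mpfConfig(dcnn = dcnnConfig(epochs = 8L, patience = 3L))

easyBenchmark <- function() {
  if (is.null(.bench$records)) {
    .bench$records <- phantomStackDataset(
      nScans = 151L, objectsPerScan = 4L, separability = "easy", seed = 404L)
    .bench$split <- splitDataset(.bench$records, 0.7, seed = 404L)
  }
  list(records = .bench$records, split = .bench$split)
}

benchmarkRuns <- function() {
  if (is.null(.bench$runs)) {
    b <- easyBenchmark()
    cfg <- benchConfig()
    .bench$runs <- lapply(1:3, function(s) {
      model <- trainMpf(b$records[b$split$train], cfg, seed = 100L + s)
      list(model = model,
           report = levelReport(model, b$records[b$split$test]))
    })
  }
  .bench$runs
}

benchLabels <- function(records) {
  vapply(records, function(r) r$label, character(1))
}

# a deterministic pseudo-random score in (0, 1) derived from an object id
hashScore <- function(id, salt) {
  v <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id))) * 31 + salt * 7919
  ((v %% 9973) + 0.5) / 9973
}
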