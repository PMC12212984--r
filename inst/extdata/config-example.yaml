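# Annotated pamdiv pipeline configuration.
# Any key omitted here falls back to default_config().

seed: 1                      # global seed: scenario draws + Monte-Carlo tests
out_dir: pamdiv-run          # all tables, figures and the manifest go here

# Stages to execute, in order. Drop "simulate" and provide `inputs:` below to
# analyse your own detection tables instead of the synthetic scenario.
stages: [simulate, summarize, turnover, ctree, niche]

scenario:
  preset: shelfbreak         # the built-in 10-site, 15-category community
  boundary: logistic         # "logistic" (1 deg soft range edges) or "hard"

# Uncomment to analyse real data (CSV layouts documented in ?detection_io):
# inputs:
#   detections: data/detections.csv   # site,date,category,present
#   effort: data/effort.csv           # site,date (one row per monitored day)
#   sites: data/sites.csv             # name,latitude,longitude,depth
#   categories: data/categories.csv   # id,label,guild,kind

turnover:
  span: 0.25                 # LOESS span of the display trend curves

ctree:
  configs: [full, stump, mysticete]  # tree bundles to fit (see ?tree_config)
  include_mixed: false       # include the mixed Gervais'/True's covariate?

niche:
  bands: null                # path to bands.csv, or null for the shipped
                             # placeholder band table (replace for real data)
  f_min_hz: 10               # frequency axis of the box display
  f_max_hz: 150000
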