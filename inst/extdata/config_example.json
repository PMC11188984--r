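{
  "_description": "Pipeline configuration. Every key is optional; omitted keys take the defaults of prongscape::default_config(). Units: cell_size m, buffer_km km, density_radius m, rate_hours h.",
  "seed": 7,
  "out_dir": "run",
  "simulate": true,
  "grid": { "n_rows": 100, "n_cols": 100, "cell_size": 100 },
  "n_occurrences": 1500,
  "n_historical": 200,
  "n_supplement_pool": 60,
  "supplement_n": 20,
  "era_cutoff": 1950,
  "min_year": 1980,
  "max_precision_m": 500,
  "lon_max": null,
  "n_individuals": 8,
  "n_steps": 150,
  "rate_hours": 2,
  "k_random": 15,
  "ssf_min_points": 100,
  "reg_grid": [0.5, 1.0, 1.5, 2.0, 2.5, 3.0],
  "features": ["linear", "quadratic"],
  "buffer_km": 25,
  "checkerboard_factor": 10,
  "hss_retained": 0.85,
  "lss_retained": 0.95,
  "habitat_retained": 0.99,
  "n_gcm": 3,
  "mop_fraction": 0.10,
  "mop_rows": 2000,
  "rf_trees": 200,
  "conflict_threshold": 0.5,
  "density_radius": 1000,
  "rsf_covariates": ["road_dist", "road_density", "agriculture", "barren", "grass", "shrub", "urban"],
  "ssf_covariates": ["road_dist", "road_dist_all", "road_density", "elev", "slope", "tpi", "agriculture", "barren", "grass", "shrub", "urban"],
  "write_geotiffs": true
}
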