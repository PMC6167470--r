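// Cohort-scale engine for the stochastic dark-zone/light-zone germinal-centre
// model. Mirrors the event logic of the R reference engine (R/gc_state.R,
// R/staining.R) but keeps the whole trajectory in native vectors so that
// thousand-GC cohorts are affordable. All randomness flows through R's RNG,
// so set.seed() on the R side makes runs reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Config {
  double duration, dt;
  double founder_rate, influx_window;
  int initial_divisions;
  double dz_division_rate, mutation_prob;
  double sel_rate, tfh_capacity, antigen_tau, antigen_rise;
  double lz_max_dwell, lz_death_rate, p_recycle;
  double d_min, d_max;
  bool affinity_dependent;
  int dim;
  double gamma;
  double founder_dmin, founder_dmax;
};

Config parse_config(const List& cl) {
  Config c;
  c.duration = as<double>(cl["duration"]);
  c.dt = as<double>(cl["dt"]);
  c.founder_rate = as<double>(cl["founder_rate"]);
  c.influx_window = as<double>(cl["influx_window"]);
  c.initial_divisions = as<int>(cl["initial_divisions"]);
  c.dz_division_rate = as<double>(cl["dz_division_rate"]);
  c.mutation_prob = as<double>(cl["mutation_prob"]);
  c.sel_rate = as<double>(cl["sel_rate"]);
  c.tfh_capacity = as<double>(cl["tfh_capacity"]);
  c.antigen_tau = as<double>(cl["antigen_tau"]);
  c.antigen_rise = as<double>(cl["antigen_rise"]);
  c.lz_max_dwell = as<double>(cl["lz_max_dwell"]);
  c.lz_death_rate = as<double>(cl["lz_death_rate"]);
  c.p_recycle = as<double>(cl["p_recycle"]);
  c.d_min = as<double>(cl["d_min"]);
  c.d_max = as<double>(cl["d_max"]);
  c.affinity_dependent = as<bool>(cl["affinity_dependent"]);
  c.dim = as<int>(cl["shape_dim"]);
  c.gamma = as<double>(cl["gamma"]);
  NumericVector fd = cl["founder_dist"];
  c.founder_dmin = fd[0];
  c.founder_dmax = fd[1];
  return c;
}

struct Protocol {
  int mode;  // 0 none, 1 founder, 2 one_shot, 3 decay
  std::vector<double> probs;  // [0] = black
  double t_start, f_stained, tau, stop, dt_stain;
  bool restain;
  bool has_t0;
  double lineage_t0;
  double p0dt;  // initial per-call staining probability

  // cumulative per-call staining probability spent strictly before time t;
  // decay-mode founders arriving mid-window carry this as entry staining,
  // since tamoxifen exposure is systemic, not GC-restricted
  double spent_hazard(double t) const {
    if (mode != 3 || t <= t_start + 1e-9) return 0.0;
    double horizon = std::min(t, t_start + stop);
    int m = static_cast<int>(std::ceil((horizon - t_start) / dt_stain - 1e-9));
    double q = std::exp(-dt_stain / tau);
    double h = p0dt * (1.0 - std::pow(q, m)) / (1.0 - q);
    return h > 1.0 ? 1.0 : h;
  }
};

Protocol parse_protocol(const List& pl) {
  Protocol p;
  std::string m = as<std::string>(pl["mode"]);
  p.mode = m == "founder" ? 1 : m == "one_shot" ? 2 : m == "decay" ? 3 : 0;
  NumericVector pr = pl["probabilities"];
  p.probs.assign(pr.begin(), pr.end());
  p.t_start = as<double>(pl["t_start"]);
  p.f_stained = as<double>(pl["f_stained"]);
  p.tau = as<double>(pl["tau_tamoxifen"]);
  p.stop = as<double>(pl["tau_stainstop"]);
  p.dt_stain = as<double>(pl["dt_stain"]);
  p.restain = as<bool>(pl["allow_restain"]);
  double t0 = as<double>(pl["lineage_t0"]);
  p.has_t0 = R_finite(t0);
  p.lineage_t0 = t0;
  p.p0dt = p.mode == 3
    ? p.f_stained / (p.tau * (1.0 - std::exp(-p.stop / p.tau)))
    : 0.0;
  return p;
}

struct Pop {
  std::vector<int> cell_id, clone_id, lineage_id, div_left, color, stain_count;
  std::vector<double> birth, lz_time, help;
  std::vector<signed char> zone, lin_late, stain_tried;
  std::vector<int> pos;  // n * dim, row-major
  int dim;
  size_t n() const { return cell_id.size(); }
};

struct GC {
  Pop pop;
  double time = 0.0;
  int next_cell = 1, next_clone = 1, next_lineage = 1;
  long long n_output = 0;
  long long n_influx = 0, n_divisions = 0, n_deaths = 0;
  bool lineages_defined = false;
  std::vector<int> founder_clone;
  std::vector<double> founder_time;
  std::vector<signed char> founder_late;
  bool track_gene = false;
  std::vector<int> g_child, g_parent, g_clone;
  std::vector<double> g_time;
};

double affinity_of(const Pop& p, size_t i, const Config& c) {
  double s2 = 0.0;
  for (int k = 0; k < c.dim; ++k) {
    double d = p.pos[i * c.dim + k];
    s2 += d * d;
  }
  return std::exp(-s2 / (c.gamma * c.gamma));
}

int draw_visible(const std::vector<double>& probs) {
  double tot = 0.0;
  for (size_t k = 1; k < probs.size(); ++k) tot += probs[k];
  double u = unif_rand() * tot, acc = 0.0;
  for (size_t k = 1; k < probs.size(); ++k) {
    acc += probs[k];
    if (u <= acc) return static_cast<int>(k);
  }
  return static_cast<int>(probs.size()) - 1;
}

int draw_full(const std::vector<double>& probs) {
  double tot = 0.0;
  for (double q : probs) tot += q;
  double u = unif_rand() * tot, acc = 0.0;
  for (size_t k = 0; k < probs.size(); ++k) {
    acc += probs[k];
    if (u <= acc) return static_cast<int>(k);
  }
  return static_cast<int>(probs.size()) - 1;
}

void add_cell(GC& gc, int clone, int lineage, signed char late, int color,
              signed char zone, int divl, double birth, const int* posv,
              signed char tried, int stain_count, int parent) {
  Pop& p = gc.pop;
  int id = gc.next_cell++;
  p.cell_id.push_back(id);
  p.clone_id.push_back(clone);
  p.lineage_id.push_back(lineage);
  p.lin_late.push_back(late);
  p.color.push_back(color);
  p.zone.push_back(zone);
  p.div_left.push_back(divl);
  p.birth.push_back(birth);
  p.lz_time.push_back(0.0);
  p.help.push_back(0.0);
  p.stain_tried.push_back(tried);
  p.stain_count.push_back(stain_count);
  for (int k = 0; k < p.dim; ++k) p.pos.push_back(posv[k]);
  if (gc.track_gene) {
    gc.g_child.push_back(id);
    gc.g_parent.push_back(parent);
    gc.g_time.push_back(birth);
    gc.g_clone.push_back(clone);
  }
}

void sample_founder_pos(std::vector<int>& out, const Config& c) {
  int r = static_cast<int>(std::ceil(c.founder_dmax));
  double lo2 = c.founder_dmin * c.founder_dmin;
  double hi2 = c.founder_dmax * c.founder_dmax;
  for (;;) {
    double s2 = 0.0;
    for (int k = 0; k < c.dim; ++k) {
      int v = static_cast<int>(unif_rand() * (2 * r + 1)) - r;
      out[k] = v;
      s2 += static_cast<double>(v) * v;
    }
    if (s2 >= lo2 && s2 <= hi2) return;
  }
}

void influx(GC& gc, const Config& c, const Protocol& pr, double dt) {
  if (dt <= 0 || gc.time >= c.influx_window) return;
  int k = static_cast<int>(R::rpois(c.founder_rate * dt));
  std::vector<int> pv(c.dim);
  for (int j = 0; j < k; ++j) {
    sample_founder_pos(pv, c);
    int col = 0;
    signed char tried = 0;
    if (pr.mode == 1) {
      col = draw_full(pr.probs);
      tried = 1;
    } else if (pr.mode == 3) {
      double h = pr.spent_hazard(gc.time);
      if (h > 0 && unif_rand() < h) {
        col = draw_visible(pr.probs);
        tried = 1;
      }
    }
    int lin = NA_INTEGER;
    signed char late = 0;
    if (gc.lineages_defined) {
      lin = gc.next_lineage++;
      late = 1;
    }
    int clone = gc.next_clone++;
    add_cell(gc, clone, lin, late, col, 0, c.initial_divisions, gc.time,
             pv.data(), tried, col > 0 ? 1 : 0, NA_INTEGER);
    gc.founder_clone.push_back(clone);
    gc.founder_time.push_back(gc.time);
    gc.founder_late.push_back(gc.lineages_defined ? 1 : 0);
    gc.n_influx++;
  }
}

void define_lineages_now(GC& gc) {
  Pop& p = gc.pop;
  for (size_t i = 0; i < p.n(); ++i) {
    p.lineage_id[i] = gc.next_lineage++;
    p.lin_late[i] = 0;
  }
  gc.lineages_defined = true;
}

// One staining call. p_call is the expected fraction of the population
// recombined by this call; with restaining disabled attempts on stained
// cells are ignored, so the per-unstained-cell probability is scaled by
// N / N_unstained (capped at 1), which keeps the accumulated stained
// fraction on the calibration target.
void stain_pass(GC& gc, const Protocol& pr, double p_call, bool per_cell) {
  Pop& p = gc.pop;
  size_t n = p.n();
  if (n == 0 || p_call <= 0) return;
  size_t n_un = 0;
  for (size_t i = 0; i < n; ++i)
    if (p.color[i] == 0) ++n_un;
  double p_eff = p_call;
  if (!per_cell && n_un > 0) {
    p_eff = p_call * static_cast<double>(n) / static_cast<double>(n_un);
    if (p_eff > 1) p_eff = 1;
  }
  for (size_t i = 0; i < n; ++i) {
    if (p.color[i] == 0) {
      if (unif_rand() < p_eff) {
        p.color[i] = draw_visible(pr.probs);
        p.stain_count[i]++;
        p.stain_tried[i] = 1;
      }
    } else if (pr.restain && p.stain_count[i] > 0) {
      if (unif_rand() < p_call) {
        p.color[i] = draw_visible(pr.probs);
        p.stain_count[i]++;
      }
    }
  }
}

void maybe_mutate(Pop& p, size_t i, const Config& c) {
  if (unif_rand() < c.mutation_prob) {
    int k = static_cast<int>(unif_rand() * c.dim);
    if (k >= c.dim) k = c.dim - 1;
    p.pos[i * c.dim + k] += unif_rand() < 0.5 ? 1 : -1;
  }
}

void copy_row(Pop& p, size_t from, size_t to) {
  p.cell_id[to] = p.cell_id[from];
  p.clone_id[to] = p.clone_id[from];
  p.lineage_id[to] = p.lineage_id[from];
  p.lin_late[to] = p.lin_late[from];
  p.color[to] = p.color[from];
  p.zone[to] = p.zone[from];
  p.div_left[to] = p.div_left[from];
  p.birth[to] = p.birth[from];
  p.lz_time[to] = p.lz_time[from];
  p.help[to] = p.help[from];
  p.stain_tried[to] = p.stain_tried[from];
  p.stain_count[to] = p.stain_count[from];
  for (int k = 0; k < p.dim; ++k)
    p.pos[to * p.dim + k] = p.pos[from * p.dim + k];
}

void resize_pop(Pop& p, size_t m) {
  p.cell_id.resize(m);
  p.clone_id.resize(m);
  p.lineage_id.resize(m);
  p.lin_late.resize(m);
  p.color.resize(m);
  p.zone.resize(m);
  p.div_left.resize(m);
  p.birth.resize(m);
  p.lz_time.resize(m);
  p.help.resize(m);
  p.stain_tried.resize(m);
  p.stain_count.resize(m);
  p.pos.resize(m * p.dim);
}

void step_events(GC& gc, const Config& c) {
  Pop& p = gc.pop;
  size_t n0 = p.n();
  if (n0 == 0) {
    gc.time += c.dt;
    return;
  }
  double p_div = 1.0 - std::exp(-c.dz_division_rate * c.dt);
  double p_sel_base = 1.0 - std::exp(-c.sel_rate * c.dt);
  double p_death = 1.0 - std::exp(-c.lz_death_rate * c.dt);

  // pre-pass: light-zone mean affinity
  double asum = 0.0;
  size_t nlz = 0;
  std::vector<double> aff(n0, -1.0);
  for (size_t i = 0; i < n0; ++i) {
    if (p.zone[i] == 1) {
      aff[i] = affinity_of(p, i, c);
      asum += aff[i];
      ++nlz;
    }
  }
  double abar = nlz ? asum / nlz : 0.0;
  // limited Tfh help and decaying antigen availability; before antigen is
  // presented on FDCs neither selection tests nor death-by-neglect happen
  double rise = c.antigen_rise > 0
    ? 1.0 - std::exp(-gc.time / c.antigen_rise) : 1.0;
  double sel_scale = rise / (1.0 + static_cast<double>(nlz) / c.tfh_capacity);
  if (R_finite(c.antigen_tau)) sel_scale *= std::exp(-gc.time / c.antigen_tau);
  p_death *= rise;

  std::vector<signed char> dead(n0, 0);
  std::vector<int> buf(c.dim);
  for (size_t i = 0; i < n0; ++i) {
    if (p.zone[i] == 0) {
      if (p.div_left[i] <= 0) {
        p.zone[i] = 1;
        p.lz_time[i] = 0.0;
        continue;
      }
      if (unif_rand() < p_div) {
        p.div_left[i]--;
        for (int k = 0; k < c.dim; ++k) buf[k] = p.pos[i * c.dim + k];
        add_cell(gc, p.clone_id[i], p.lineage_id[i], p.lin_late[i],
                 p.color[i], 0, p.div_left[i], gc.time + c.dt, buf.data(),
                 p.stain_tried[i], p.stain_count[i], p.cell_id[i]);
        maybe_mutate(p, i, c);
        maybe_mutate(p, p.n() - 1, c);
        gc.n_divisions++;
      }
    } else {
      double a = aff[i];
      double ratio =
          (c.affinity_dependent && abar > 0.0) ? a / abar : 1.0;
      double psel = p_sel_base * ratio * sel_scale;
      if (psel > 1) psel = 1;
      if (unif_rand() < psel) {
        double s = c.affinity_dependent
                       ? (a + abar > 0.0 ? a / (a + abar) : 0.5)
                       : 0.5;
        if (unif_rand() < c.p_recycle) {
          p.zone[i] = 0;
          p.div_left[i] =
              static_cast<int>(std::lround(c.d_min + (c.d_max - c.d_min) * s));
          p.help[i] = s;
        } else {
          dead[i] = 1;
          gc.n_output++;
        }
      } else {
        p.lz_time[i] += c.dt;
        if (p.lz_time[i] > c.lz_max_dwell && unif_rand() < p_death) {
          dead[i] = 1;
          gc.n_deaths++;
        }
      }
    }
  }
  // compact; daughters appended beyond n0 are all alive
  size_t n1 = p.n(), w = 0;
  for (size_t i = 0; i < n1; ++i) {
    bool keep = (i >= n0) || !dead[i];
    if (keep) {
      if (w != i) copy_row(p, i, w);
      ++w;
    }
  }
  resize_pop(p, w);
  gc.time += c.dt;
}

List snapshot(const GC& gc, const Config& c) {
  const Pop& p = gc.pop;
  size_t n = p.n();
  IntegerVector cell_id(n), clone_id(n), lineage_id(n), color(n), zone(n),
      div_left(n), stain_count(n);
  LogicalVector lin_late(n), stain_tried(n);
  NumericVector birth(n), aff(n);
  for (size_t i = 0; i < n; ++i) {
    cell_id[i] = p.cell_id[i];
    clone_id[i] = p.clone_id[i];
    lineage_id[i] = p.lineage_id[i];
    lin_late[i] = p.lin_late[i] != 0;
    color[i] = p.color[i];
    zone[i] = p.zone[i];
    div_left[i] = p.div_left[i];
    birth[i] = p.birth[i];
    stain_tried[i] = p.stain_tried[i] != 0;
    stain_count[i] = p.stain_count[i];
    aff[i] = affinity_of(p, i, c);
  }
  return List::create(
      _["t"] = gc.time, _["cell_id"] = cell_id, _["clone_id"] = clone_id,
      _["lineage_id"] = lineage_id, _["lineage_late"] = lin_late,
      _["color"] = color, _["zone"] = zone, _["divisions_left"] = div_left,
      _["birth_time"] = birth, _["stain_tried"] = stain_tried,
      _["stain_count"] = stain_count, _["affinity"] = aff);
}

List full_state(const GC& gc, const Config& c) {
  const Pop& p = gc.pop;
  size_t n = p.n();
  List snap = snapshot(gc, c);
  IntegerMatrix pos(n, c.dim);
  NumericVector lz_time(n), help(n);
  for (size_t i = 0; i < n; ++i) {
    lz_time[i] = p.lz_time[i];
    help[i] = p.help[i];
    for (int k = 0; k < c.dim; ++k) pos(i, k) = p.pos[i * c.dim + k];
  }
  return List::create(
      _["time"] = gc.time, _["snapshot"] = snap, _["pos"] = pos,
      _["lz_time"] = lz_time, _["help"] = help,
      _["next_cell_id"] = gc.next_cell, _["next_clone_id"] = gc.next_clone,
      _["next_lineage_id"] = gc.next_lineage,
      _["n_output"] = static_cast<double>(gc.n_output),
      _["lineages_defined"] = gc.lineages_defined,
      _["counts"] = NumericVector::create(
          _["influx"] = static_cast<double>(gc.n_influx),
          _["divisions"] = static_cast<double>(gc.n_divisions),
          _["deaths"] = static_cast<double>(gc.n_deaths),
          _["output"] = static_cast<double>(gc.n_output)));
}

bool on_grid(double t, double origin, double every, double dt) {
  if (every <= 0) return false;
  double k = std::floor((t - origin) / every + 0.5);
  return k >= 0 && std::fabs(t - (origin + k * every)) < dt / 2.0;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_run_gc")]]
List cpp_run_gc(List config, List protocol, NumericVector record_times,
                double kinetics_every = -1.0, bool genealogy = false) {
  Config c = parse_config(config);
  Protocol pr = parse_protocol(protocol);
  GC gc;
  gc.pop.dim = c.dim;
  gc.track_gene = genealogy;

  std::vector<double> rt(record_times.begin(), record_times.end());
  std::sort(rt.begin(), rt.end());
  size_t ri = 0;
  bool shot_done = false;

  long long nsteps = static_cast<long long>(std::floor(c.duration / c.dt + 0.5));
  List snaps(rt.size());
  std::vector<double> kin_t, kin_n, kin_aff, kin_out;

  for (long long step = 0; step <= nsteps; ++step) {
    double t = step * c.dt;
    gc.time = t;
    while (ri < rt.size() && std::fabs(rt[ri] - t) < c.dt / 2.0) {
      snaps[ri] = snapshot(gc, c);
      ++ri;
    }
    if (kinetics_every > 0 && on_grid(t, 0.0, kinetics_every, c.dt)) {
      double asum = 0.0;
      size_t n = gc.pop.n();
      for (size_t i = 0; i < n; ++i) asum += affinity_of(gc.pop, i, c);
      kin_t.push_back(t);
      kin_n.push_back(static_cast<double>(n));
      kin_aff.push_back(n ? asum / n : NA_REAL);
      kin_out.push_back(static_cast<double>(gc.n_output));
    }
    if (step == nsteps) break;

    influx(gc, c, pr, c.dt);
    if (!gc.lineages_defined && pr.has_t0 && t >= pr.lineage_t0 - 1e-9) {
      define_lineages_now(gc);
    }
    if (pr.mode == 3) {
      if (t >= pr.t_start - 1e-9 && t < pr.t_start + pr.stop - 1e-9 &&
          on_grid(t, pr.t_start, pr.dt_stain, c.dt)) {
        double p_call =
            pr.p0dt * std::exp(-(t - pr.t_start) / pr.tau);
        stain_pass(gc, pr, p_call, false);
      }
    } else if (pr.mode == 2 && !shot_done && t >= pr.t_start - 1e-9) {
      stain_pass(gc, pr, pr.f_stained, true);
      shot_done = true;
    }
    step_events(gc, c);
  }

  List kinetics = List::create(
      _["t"] = wrap(kin_t), _["n"] = wrap(kin_n),
      _["mean_affinity"] = wrap(kin_aff), _["n_output"] = wrap(kin_out));

  List gene = R_NilValue;
  if (genealogy) {
    size_t m = gc.g_child.size();
    IntegerVector ch(m), pa(m), cl(m);
    NumericVector tm(m);
    for (size_t i = 0; i < m; ++i) {
      ch[i] = gc.g_child[i];
      pa[i] = gc.g_parent[i];
      cl[i] = gc.g_clone[i];
      tm[i] = gc.g_time[i];
    }
    gene = List::create(_["cell_id"] = ch, _["parent_id"] = pa,
                        _["birth_time"] = tm, _["clone_id"] = cl);
  }

  size_t nf = gc.founder_clone.size();
  IntegerVector fc(nf);
  NumericVector ft(nf);
  LogicalVector fl(nf);
  for (size_t i = 0; i < nf; ++i) {
    fc[i] = gc.founder_clone[i];
    ft[i] = gc.founder_time[i];
    fl[i] = gc.founder_late[i] != 0;
  }

  return List::create(
      _["snapshots"] = snaps, _["state"] = full_state(gc, c),
      _["founder_log"] = List::create(_["clone_id"] = fc,
                                      _["entry_time"] = ft, _["late"] = fl),
      _["kinetics"] = kinetics, _["genealogy"] = gene);
}
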