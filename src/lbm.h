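#ifndef CELLSQ_LBM_H
#define CELLSQ_LBM_H

extern const int E19[19][3];
extern const double W19[19];
extern const int OPP19[19];

void lbm_step_once(double *f, double *fpost, const int *solid,
                   int Nx, int Ny, int Nz, double tau,
                   const double *gconst, const double *siteforce,
                   const int *periodic, double *minpop_out);

int trilinear_fluid(double xl, double yl, double zl, const int *solid,
                    int Nx, int Ny, int Nz, const int *periodic,
                    int idx[8], double w[8]);

#endif
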