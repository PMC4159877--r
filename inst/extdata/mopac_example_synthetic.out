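 *******************************************************************************
 **                                                                           **
 **                              MOPAC-style output                           **
 **        SYNTHETIC example file for testing the heat-of-formation parser   **
 **                 (not produced by any quantum-chemistry run)              **
 **                                                                           **
 *******************************************************************************

          GEOMETRY OPTIMISED USING EIGENVECTOR FOLLOWING (EF).
          SCF FIELD WAS ACHIEVED

          HEAT OF FORMATION IS UNRELIABLE UNTIL CONVERGED

          FINAL HEAT OF FORMATION =        123.45678 KCAL/MOL =     516.54197 KJ/MOL

          TOTAL ENERGY            =      -2345.67890 EV
          ELECTRONIC ENERGY       =     -12345.67890 EV
          IONIZATION POTENTIAL    =          8.76543 EV

 == MOPAC DONE ==
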