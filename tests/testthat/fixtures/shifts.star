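data_synthetic_shifts

save_assigned_chem_shift_list_1
   _Assigned_chem_shift_list.Sf_category   assigned_chemical_shifts

   loop_
      _Atom_chem_shift.Entry_ID
      _Atom_chem_shift.Comp_ID
      _Atom_chem_shift.Atom_ID
      _Atom_chem_shift.Val
      _Atom_chem_shift.Chem_shift_reference

      901 LYS CE 41.85 DSS
      901 LYS CE 42.10 DSS
      902 LYS CE 43.60 TMS
      902 ARG CZ 159.75 DSS
      903 ARG CZ 161.40 TMS
      903 SER CB 63.70 TSP
      904 THR CB 69.55 DSS
   stop_
save_
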