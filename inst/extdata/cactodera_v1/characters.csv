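id,label,stage,kind,units,categories
cyst_length,Cyst length (excluding neck),cyst,numeric,um,
cyst_width,Cyst width (Diam.),cyst,numeric,um,
cyst_lw_ratio,Cyst L/W ratio (L/Diam.),cyst,numeric,ratio,
fenestral_diam,Fenestral diameter,cyst,numeric,um,
vulval_denticles,Vulval denticles,cyst,categorical,,present;absent
vulval_cone,Vulval cone prominence,cyst,categorical,,distinct;indistinct
j2_length,J2 body length,J2,numeric,um,
j2_width,J2 body width at mid-body,J2,numeric,um,
a_ratio,de Man a (body length / max body width),J2,numeric,ratio,
b_ratio,de Man b (body length / pharynx length),J2,numeric,ratio,
c_ratio,de Man c (body length / tail length),J2,numeric,ratio,
c_prime,de Man c' (tail length / anal body diameter),J2,numeric,ratio,
lip_height,Lip region height,J2,numeric,um,
lip_diam,Lip region diameter,J2,numeric,um,
stylet_length,J2 stylet length,J2,numeric,um,
stylet_base_height,Stylet base height,J2,numeric,um,
stylet_base_width,Stylet base width,J2,numeric,um,
stylet_knob_shape,Anterior surface of stylet knobs,J2,categorical,,concave;convex
mb,Median bulb from anterior end (MB),J2,numeric,um,
mbw,Median bulb width (MBW),J2,numeric,um,
dgo,Dorsal pharyngeal gland opening from stylet base (DGO),J2,numeric,um,
ep,Excretory pore from anterior end (EP),J2,numeric,um,
anal_diam,Body diameter at anus,J2,numeric,um,
tail_length,J2 tail length,J2,numeric,um,
hyaline_length,J2 hyaline tail length (H),J2,numeric,um,
l_over_mb,L/MB ratio,J2,numeric,ratio,
tl_over_h,TL/H ratio,J2,numeric,ratio,
eggshell_surface,Eggshell surface,egg,categorical,,smooth;punctate
egg_length,Egg length,egg,numeric,um,
egg_width,Egg width,egg,numeric,um,
egg_lw_ratio,Egg length/width ratio,egg,numeric,ratio,
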