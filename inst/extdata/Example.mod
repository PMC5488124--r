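import nsrunit; unit conversion on;   // Use cgs units
math example {                        // model declaration
// INDEPENDENT VARIABLES
realDomain t s; t.min=0; t.max=16; t.delta = 0.1;
//%START a2bParmsVars       // Specify parameters and variables sect.
// PARAMETERS
real Flow = 1 ml/(g*min);   // Flow rate
real PSA12 = 6 ml/(g*min);  // Conductance
real PSB12 = 5 ml/(g*min);  // Conductance
real PSC12 = 4 ml/(g*min);  // Conductance
real V1 = 0.05 ml/g;        // Volume
real V2 = 0.05 ml/g;        // Volume
extern real Ain(t) mM;    // Inflow concentration of solute A
extern real Bin(t) mM;    // Inflow concentration of B, set to zero
extern real Cin(t) mM;    // Inflow concentration of C, set to zero
// DEPENDENT VARIABLES
real A1(t) mM; real B1(t) mM; real C1(t) mM; // Concentrations in V1
real A2(t) mM; real B2(t) mM; real C2(t) mM; // Concentrations in V2
// INITIAL CONDITIONS (IC's)
when(t=t.min)  A1=0;
when(t=t.min)  A2=0;
when(t=t.min)  B1=0;
when(t=t.min)  B2=0;
when(t=t.min)  C1=0;
when(t=t.min)  C2=0;
//%END a2bParmsVars    // End parameters and variables section
//%START a2bCalc       // Specify calculations section
real Ga2b = 5 ml/(g*min);   // A ->B First order reaction rate.
real KmB2 =1.0 mM, VmaxB2 =2 umol/(g*min);// Michaelis const; max velocity of rxn
real Gb2c(t) ml/(g*min);                  // B ->C Michaelis Menten reaction rate
Gb2c = (VmaxB2/(KmB2+B2));
// ODE CALCULATIONS
A2:t = -Ga2b/V2*A2 +PSA12/V2*(A1-A2);
B2:t = Ga2b/V2*A2 -Gb2c*(B2)/V2 +PSB12/V2*(B1-B2);
C2:t = Gb2c*(B2)/V2 +PSC12/V2*(C1-C2);
A1:t = (Flow/V1)*(Ain-A1) +PSA12/V1*(A2-A1);
B1:t = (Flow/V1)*(Bin-B1) +PSB12/V1*(B2-B1);
C1:t = (Flow/V1)*(Cin-C1) +PSC12/V1*(C2-C1);
// %END a2bCalc
}   // curly bracket ends model
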